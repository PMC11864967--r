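# Independent brute-force kinship oracle: exhaustive enumeration of
# ancestral path pairs (Wright's method).  phi(i, j) = sum over common
# ancestors A and pairs of descending paths from A to i and j that share
# no node but A of (1/2)^(n1 + n2 + 1) * (1 + F_A), with n the number of
# links per path.  Exponential, only for small pedigrees.

oracle_children <- function(df) {
  ch <- lapply(df$id, function(p) {
    df$id[(!is.na(df$father) & df$father == p) |
            (!is.na(df$mother) & df$mother == p)]
  })
  names(ch) <- df$id
  ch
}

oracle_ancestors <- function(df, i) {
  out <- i
  queue <- i
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    r <- df[df$id == q, ]
    for (p in c(r$father, r$mother)) {
      if (!is.na(p) && !(p %in% out)) {
        out <- c(out, p); queue <- c(queue, p)
      }
    }
  }
  out
}

# all descending node sequences from a to b (a first, b last)
oracle_paths_down <- function(df, a, b, children) {
  if (a == b) return(list(a))
  out <- list()
  for (ch in children[[a]]) {
    for (tail in oracle_paths_down(df, ch, b, children)) {
      out[[length(out) + 1L]] <- c(a, tail)
    }
  }
  out
}

oracle_inbreeding <- function(df, i) {
  r <- df[df$id == i, ]
  if (is.na(r$father) || is.na(r$mother)) return(0)
  oracle_kinship(df, r$father, r$mother)
}

oracle_kinship <- function(df, i, j) {
  if (i == j) return(0.5 * (1 + oracle_inbreeding(df, i)))
  children <- oracle_children(df)
  common <- intersect(oracle_ancestors(df, i), oracle_ancestors(df, j))
  phi <- 0
  for (A in common) {
    pi_ <- oracle_paths_down(df, A, i, children)
    pj_ <- oracle_paths_down(df, A, j, children)
    FA <- oracle_inbreeding(df, A)
    for (p1 in pi_) {
      for (p2 in pj_) {
        if (length(intersect(p1[-1], p2[-1])) == 0) {
          phi <- phi + 0.5^(length(p1) + length(p2) - 1) * (1 + FA)
        }
      }
    }
  }
  phi
}

# random acyclic pedigree with n_founder founders and n_child children
# drawn over previous members; used for property tests
random_pedigree_df <- function(n_founders = 4, n_children = 8) {
  id <- sprintf("P%02d", seq_len(n_founders + n_children))
  sex <- c(rep(c("male", "female"), length.out = n_founders),
           sample(c("male", "female"), n_children, replace = TRUE))
  father <- rep(NA_character_, n_founders + n_children)
  mother <- rep(NA_character_, n_founders + n_children)
  for (k in seq_len(n_children)) {
    i <- n_founders + k
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    if (!length(males) || !length(females)) next
    father[i] <- id[males[sample.int(length(males), 1)]]
    mother[i] <- id[females[sample.int(length(females), 1)]]
  }
  data.frame(id = id, father = father, mother = mother, sex = sex,
             stringsAsFactors = FALSE)
}

# first-cousin mating pedigree: x is the child of full first cousins
cousin_marriage_df <- function() {
  data.frame(
    id = c("gf", "gm", "s1", "s2", "w1", "w2", "c1", "c2", "x"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "female", "male"),
    father = c(NA, NA, "gf", "gf", NA, NA, "s1", "s2", "c1"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "w1", "w2", "c2"),
    stringsAsFactors = FALSE)
}

# shared simulated community fixtures, built once per test run
.fixtures <- new.env()

std_community <- function() {
  if (is.null(.fixtures$com)) {
    com <- simulate_community(community_config(seed = 2))
    stopifnot(!com$extinct)
    .fixtures$com <- drop_genomes(com)
  }
  .fixtures$com
}

std_observed <- function() {
  if (is.null(.fixtures$obs)) {
    .fixtures$obs <- observe(std_community(), degree_noise = 0, seed = 5)
  }
  .fixtures$obs
}

std_reconstruction <- function() {
  if (is.null(.fixtures$rec)) {
    obs <- std_observed()
    .fixtures$rec <- reconstruct_pedigree(obs$degrees, obs$metadata,
                                          ibd = obs$ibd)
  }
  .fixtures$rec
}

# simulate with retries over consecutive seeds until non-extinct
simulate_nonextinct <- function(config_args = list(), seed = 1L,
                                max_tries = 10L) {
  for (k in seq_len(max_tries)) {
    cfg <- do.call(community_config, c(config_args, list(seed = seed + k - 1L)))
    com <- simulate_community(cfg)
    if (!com$extinct) return(com)
  }
  stop("no non-extinct community in ", max_tries, " tries")
}
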