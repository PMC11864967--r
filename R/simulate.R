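## Forward simulator of a patrilocal burial community.  Men stay on site
## and marry in brides from outside (female exogamy); daughters mostly
## leave to marry elsewhere.  Polygyny and levirate re-partnering create
## multi-reproductive unions.  The simulator records complete ground
## truth (pedigree, unions, levirate events) against which every analysis
## stage is validated.

## deterministic per-stage substreams derived from one base seed
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.double(seed) * 7919 + h %% 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

DEFAULT_MORTALITY <- c("inf I" = 0.25, "inf II" = 0.08, "juv" = 0.05,
                       "ya" = 0.12, "yma" = 0.15, "ma" = 0.20, "oa" = 0.15)
ADULT_CATEGORIES <- c("ya", "yma", "ma", "oa")
AGE_RANGES <- list("inf I" = c(0, 6), "inf II" = c(7, 13), "juv" = c(14, 17),
                   "ya" = c(18, 25), "yma" = c(26, 35), "ma" = c(36, 50),
                   "oa" = c(50, 70))

#' Community simulation configuration
#'
#' Parameters of the forward simulator.  Defaults describe a six-
#' generation patrilocal community of a size comparable to a fully
#' excavated early-medieval cemetery (roughly 150 residents): strong male
#' residence and female exogamy, occasional polygyny, levirate
#' re-partnering after early male death, one dominant founder Y lineage
#' and East Asian-dominant ancestry with exogamous brides of similar
#' ancestry.
#'
#' @param n_generations Number of generations simulated (>= 1).
#' @param founder_couples Founding couples in generation 1.
#' @param p_son_stays Probability an adult son stays on site
#'   (patrilocality).
#' @param p_daughter_leaves Probability an adult daughter leaves to marry
#'   elsewhere (female exogamy).
#' @param p_local_union Probability a staying man marries an available
#'   unrelated local woman instead of an exogamous bride.
#' @param p_polygyny Probability a married man takes an additional
#'   exogamous partner.
#' @param p_levirate Probability the widow of a man who died young
#'   re-partners with a male relative of the deceased (brother,
#'   half-brother or stepson; later generations allowed).
#' @param fertility_mean Mean children per union (Poisson).
#' @param mortality_table Named probabilities over the seven age
#'   categories; must sum to 1.
#' @param sampling_prob Probability a deceased community member is buried
#'   and sampled on site.
#' @param founder_y_pool Named Y-haplogroup frequencies for founder men
#'   (default one dominant lineage).
#' @param bride_mt_pool mtDNA haplogroup labels available to exogamous
#'   brides (sampled uniformly).
#' @param founder_ancestry,bride_ancestry Ancestry proportions
#'   (East Asian, European, Steppe) of founder men and incoming brides.
#' @param status_item_probs Probability that a sampled adult carries the
#'   sex-linked prestige object (`belt_set` for men, `coat_clasp` for
#'   women).
#' @param site Site code used for residents.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return Object of class `community_config`.
#' @export
community_config <- function(n_generations = 6L, founder_couples = 4L,
                             p_son_stays = 0.85, p_daughter_leaves = 0.85,
                             p_local_union = 0.15, p_polygyny = 0.10,
                             p_levirate = 0.15, fertility_mean = 4.0,
                             mortality_table = DEFAULT_MORTALITY,
                             sampling_prob = 1,
                             founder_y_pool = c("Y-C2b" = 0.8, "Y-R1a" = 0.1,
                                                "Y-N1a" = 0.1),
                             bride_mt_pool = paste0("mt-", c("A", "B", "C4",
                               "D4", "F1", "G2", "H", "HV", "J1", "K1", "T2",
                               "U5")),
                             founder_ancestry = c(EastAsian = 0.75,
                                                  European = 0.15,
                                                  Steppe = 0.10),
                             bride_ancestry = c(EastAsian = 0.70,
                                                European = 0.20,
                                                Steppe = 0.10),
                             status_item_probs = c(belt_set = 0.3,
                                                   coat_clasp = 0.3),
                             site = "SIM", seed = 1L) {
  probs <- c(p_son_stays, p_daughter_leaves, p_local_union, p_polygyny,
             p_levirate, sampling_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_generations < 1L) stop("n_generations must be >= 1")
  if (!setequal(names(mortality_table), AGE_CATEGORIES)) {
    stop("mortality_table must name all seven age categories")
  }
  if (abs(sum(mortality_table) - 1) > 1e-9) {
    stop("mortality_table must sum to 1")
  }
  for (a in list(founder_ancestry, bride_ancestry)) {
    if (abs(sum(a) - 1) > 1e-9) stop("ancestry proportions must sum to 1")
  }
  cfg <- as.list(environment())[names(formals(community_config))]
  cfg$n_generations <- as.integer(n_generations)
  cfg$founder_couples <- as.integer(founder_couples)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "community_config"
  cfg
}

#' Simulate a patrilocal community
#'
#' Runs the generation loop: staying men take exogamous brides (or,
#' occasionally, unrelated local women), draw Poisson child counts, may
#' add polygynous partners; widows of men who died young may re-partner
#' with a relative of the deceased (levirate).  mtDNA passes from mother
#' to child and Y from father to son; a child's ancestry is the mean of
#' its parents'.  Ages at death are drawn from the mortality table;
#' reproduction requires surviving to adulthood.  Deceased residents are
#' buried and sampled with `sampling_prob`; emigrants are never sampled.
#'
#' @param config A [community_config()].
#' @return Object of class `simulated_community`: `pedigree` (all
#'   individuals, residents and emigrants), `unions` and `levirates`
#'   truth tables, `extinct` flag with `generations_completed`, and the
#'   `config`.  If the community dies out before `n_generations` the
#'   partial community is returned with `extinct = TRUE`.
#' @export
simulate_community <- function(config = community_config()) {
  with_seed(substream_seed(config$seed, "simulate"), {
    sim_community_impl(config)
  })
}

sim_community_impl <- function(config) {
  env <- new.env()
  env$rows <- list()
  env$n <- 0L
  env$unions <- list()
  env$levirates <- list()

  draw_age <- function(adult = FALSE) {
    tab <- config$mortality_table[AGE_CATEGORIES]
    if (adult) {
      tab <- tab[ADULT_CATEGORIES] / sum(tab[ADULT_CATEGORIES])
    }
    cat <- sample(names(tab), 1L, prob = tab)
    rng <- AGE_RANGES[[cat]]
    age <- stats::runif(1, rng[1], rng[2])
    list(category = cat, age = age, low = rng[1], high = rng[2])
  }

  new_person <- function(sex, gen, father = NA_character_,
                         mother = NA_character_, mt = NA_character_,
                         y = NA_character_, anc, adult = FALSE,
                         resident = TRUE) {
    env$n <- env$n + 1L
    id <- sprintf("%s%03d", config$site, env$n)
    a <- draw_age(adult)
    env$rows[[id]] <- list(id = id, father = father, mother = mother,
                           sex = sex, gen = gen, mt_hap = mt,
                           y_hap = if (sex == "male") y else NA_character_,
                           anc = anc, age = a$age, age_category = a$category,
                           age_low = a$low, age_high = a$high,
                           resident = resident)
    id
  }

  person <- function(id) env$rows[[id]]
  set_field <- function(id, field, value) env$rows[[id]][[field]] <- value

  add_union <- function(father, mother, gen, type, n_children = NULL) {
    if (is.null(n_children)) n_children <- stats::rpois(1, config$fertility_mean)
    kids <- character(0)
    if (n_children > 0) {
      f <- person(father); m <- person(mother)
      for (k in seq_len(n_children)) {
        sex <- sample(c("male", "female"), 1L)
        kids <- c(kids, new_person(sex, gen + 1L, father = father,
                                   mother = mother, mt = m$mt_hap,
                                   y = f$y_hap, anc = (f$anc + m$anc) / 2))
      }
    }
    env$unions[[length(env$unions) + 1L]] <-
      list(father = father, mother = mother, generation = gen, type = type,
           children = kids)
    kids
  }

  new_bride <- function(gen) {
    new_person("female", gen, mt = sample(config$bride_mt_pool, 1L),
               anc = config$bride_ancestry, adult = TRUE)
  }

  ## generation 1: founder couples
  for (k in seq_len(config$founder_couples)) {
    m <- new_person("male", 1L, mt = sample(config$bride_mt_pool, 1L),
                    y = sample(names(config$founder_y_pool), 1L,
                               prob = config$founder_y_pool),
                    anc = config$founder_ancestry, adult = TRUE)
    b <- new_bride(1L)
    set_field(m, "spouse", b)
  }

  ## kinship among current residents, rebuilt lazily per generation
  kin_matrix_now <- function() {
    ids <- names(env$rows)
    df <- do.call(rbind, lapply(env$rows, function(r) {
      data.frame(id = r$id, father = r$father, mother = r$mother,
                 sex = r$sex, stringsAsFactors = FALSE)
    }))
    kinship_matrix(pedigree(df, validate = FALSE))
  }

  extinct <- FALSE
  completed <- 1L
  for (g in seq_len(config$n_generations - 1L)) {
    ids <- names(env$rows)
    info <- env$rows
    is_adult <- vapply(info, function(r) r$age_category %in% ADULT_CATEGORIES,
                       logical(1))
    gen_of <- vapply(info, function(r) r$gen, integer(1))
    sex_of <- vapply(info, function(r) r$sex, character(1))
    res_of <- vapply(info, function(r) isTRUE(r$resident), logical(1))

    has_father <- vapply(info, function(r) !is.na(r$father), logical(1))
    men <- ids[sex_of == "male" & gen_of == g & is_adult & res_of]
    ## local daughters only (brides married in are already partnered)
    women <- ids[sex_of == "female" & gen_of == g & is_adult & res_of &
                   has_father]

    ## residence decisions (founders always stay)
    staying_men <- character(0)
    for (m in men) {
      if (is.na(person(m)$father) || isTRUE(person(m)$stays) ||
          stats::runif(1) < config$p_son_stays) {
        staying_men <- c(staying_men, m)
      } else {
        set_field(m, "resident", FALSE)
      }
    }
    local_women <- character(0)
    for (w in women) {
      if (stats::runif(1) < config$p_daughter_leaves) {
        set_field(w, "resident", FALSE)
      } else {
        local_women <- c(local_women, w)
      }
    }

    if (!length(staying_men)) { extinct <- TRUE; break }
    K <- kin_matrix_now()

    married_to <- list()
    for (m in staying_men) {
      ## founder wives were attached at creation
      pre <- person(m)$spouse
      bride <- NULL
      if (!is.null(pre)) {
        bride <- pre
      } else {
        eligible_local <- local_women[K[local_women, m] == 0]
        if (length(eligible_local) &&
            stats::runif(1) < config$p_local_union) {
          bride <- if (length(eligible_local) == 1L) eligible_local else
            sample(eligible_local, 1L)
          local_women <- setdiff(local_women, bride)
        } else {
          bride <- new_bride(g)
        }
      }
      kids <- add_union(m, bride, g, type = "primary")
      married_to[[m]] <- bride
      if (stats::runif(1) < config$p_polygyny) {
        b2 <- new_bride(g)
        add_union(m, b2, g, type = "polygynous")
        married_to[[m]] <- c(married_to[[m]], b2)
      }
    }

    ## levirate: widows of married men who died young re-partner with a
    ## male relative of the deceased
    K <- kin_matrix_now()
    for (m in names(married_to)) {
      died_young <- person(m)$age < 36
      if (!died_young || stats::runif(1) >= config$p_levirate) next
      for (widow in married_to[[m]]) {
        all_ids <- names(env$rows)
        cand <- Filter(function(x) {
          r <- env$rows[[x]]
          x != m && r$sex == "male" && isTRUE(r$resident) &&
            r$age_category %in% ADULT_CATEGORIES && r$gen >= person(m)$gen &&
            K_now(K, x, m) >= 1 / 8 && K_now(K, x, widow) == 0 &&
            !identical(r$mother, widow)
        }, all_ids)
        if (!length(cand)) next
        partner <- if (length(cand) == 1L) cand[[1L]] else sample(unlist(cand), 1L)
        ## fathering children on site commits the partner to residence
        set_field(partner, "stays", TRUE)
        n_kids <- max(1L, stats::rpois(1, config$fertility_mean / 2))
        add_union(partner, widow, g, type = "levirate", n_children = n_kids)
        env$levirates[[length(env$levirates) + 1L]] <-
          list(widow = widow, deceased = m, partner = partner,
               generation = g)
        break
      }
    }
    completed <- g + 1L
  }

  build_community(env, config, extinct, completed)
}

## kinship lookup tolerant of individuals added after K was built
K_now <- function(K, a, b) {
  if (a %in% rownames(K) && b %in% rownames(K)) K[a, b] else 0
}

build_community <- function(env, config, extinct, completed) {
  rows <- env$rows
  ids <- names(rows)
  anc <- t(vapply(rows, function(r) r$anc, numeric(3)))
  resident <- vapply(rows, function(r) isTRUE(r$resident), logical(1))
  sampled <- resident & stats::runif(length(ids)) < config$sampling_prob
  sex <- vapply(rows, function(r) r$sex, character(1))
  status <- character(length(ids))
  adult <- vapply(rows, function(r) r$age_category %in% ADULT_CATEGORIES,
                  logical(1))
  has_belt <- sex == "male" & adult & sampled &
    stats::runif(length(ids)) < config$status_item_probs[["belt_set"]]
  has_clasp <- sex == "female" & adult & sampled &
    stats::runif(length(ids)) < config$status_item_probs[["coat_clasp"]]
  status[has_belt] <- "belt_set"
  status[has_clasp] <- "coat_clasp"
  status[status == ""] <- NA_character_

  ind <- data.frame(
    id = ids,
    father = vapply(rows, function(r) r$father, character(1)),
    mother = vapply(rows, function(r) r$mother, character(1)),
    sex = sex,
    sampled = sampled,
    site = ifelse(resident, config$site, "away"),
    mt_hap = vapply(rows, function(r) r$mt_hap, character(1)),
    y_hap = vapply(rows, function(r) r$y_hap %||% NA_character_, character(1)),
    age_low = vapply(rows, function(r) r$age_low, numeric(1)),
    age_high = vapply(rows, function(r) r$age_high, numeric(1)),
    age_category = vapply(rows, function(r) r$age_category, character(1)),
    anc_EastAsian = anc[, 1], anc_European = anc[, 2], anc_Steppe = anc[, 3],
    status_items = status,
    grave_x = ifelse(sampled, stats::runif(length(ids), 0, 100), NA_real_),
    grave_y = ifelse(sampled, stats::runif(length(ids), 0, 100), NA_real_),
    stringsAsFactors = FALSE
  )
  ped <- pedigree(ind)

  unions <- if (length(env$unions)) {
    do.call(rbind, lapply(seq_along(env$unions), function(k) {
      u <- env$unions[[k]]
      data.frame(union_id = sprintf("U%03d", k), father = u$father,
                 mother = u$mother, generation = u$generation,
                 type = u$type, n_children = length(u$children),
                 children = paste(u$children, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(union_id = character(), father = character(),
               mother = character(), generation = integer(),
               type = character(), n_children = integer(),
               children = character(), stringsAsFactors = FALSE)
  }
  levirates <- if (length(env$levirates)) {
    do.call(rbind, lapply(env$levirates, function(l) {
      data.frame(widow = l$widow, deceased = l$deceased,
                 partner = l$partner, generation = l$generation,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(widow = character(), deceased = character(),
               partner = character(), generation = integer(),
               stringsAsFactors = FALSE)
  }

  structure(list(pedigree = ped, unions = unions, levirates = levirates,
                 extinct = extinct, generations_completed = completed,
                 config = config, genomes = NULL, genome_model = NULL),
            class = "simulated_community")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulated_community <- function(x, ...) {
  cat(sprintf("<simulated_community> %d individuals (%d sampled), %d unions, %d levirate events%s\n",
              nrow(x$pedigree$ind), sum(x$pedigree$ind$sampled),
              nrow(x$unions), nrow(x$levirates),
              if (x$extinct) sprintf(" [extinct after %d generations]",
                                     x$generations_completed) else ""))
  invisible(x)
}

## ---------------------------------------------------------------------
## Observation layer

#' Adjacent-degree confusion matrix
#'
#' Builds a confusion matrix over the ordered degree scale
#' (`identical`, `1` ... `6`, `unrelated`) in which each record keeps its
#' true degree with probability `1 - rate` and otherwise moves to an
#' adjacent degree (split evenly; all mass to the single neighbour at the
#' ends of the scale).
#'
#' @param rate Per-record perturbation probability.
#' @return Row-stochastic matrix with degree labels as dimnames.
#' @export
degree_confusion_matrix <- function(rate = 0.05) {
  k <- length(DEGREE_LEVELS)
  M <- diag(1 - rate, k)
  for (i in seq_len(k)) {
    nb <- c(i - 1L, i + 1L)
    nb <- nb[nb >= 1L & nb <= k]
    M[i, nb] <- rate / length(nb)
  }
  dimnames(M) <- list(DEGREE_LEVELS, DEGREE_LEVELS)
  M
}

#' Generate the observed dataset from a simulated community
#'
#' Produces the tables an ancient-DNA kinship workflow would start from:
#' per-individual metadata, pairwise relatedness degrees (true pedigree
#' degrees perturbed by an adjacent-degree confusion matrix, emulating
#' degree-classification noise) and pairwise IBD summaries from the
#' dropped genomes.  Unsampled individuals are removed from all tables.
#'
#' @param community A `simulated_community`.
#' @param degree_noise Either a single adjacent-swap rate or a full
#'   confusion matrix over the eight degree levels (rows must sum to 1).
#' @param drop_unsampled Remove unsampled individuals (default `TRUE`).
#' @param include_ibd Compute the pairwise IBD table (requires genomes).
#' @param ibd_min_cM Minimum IBD segment length retained.
#' @param seed Seed for the noise draws; deterministic given it.
#' @return List with `metadata`, `degrees`, `ibd` (or `NULL`) and
#'   `truth` (the unperturbed degree table).
#' @export
observe <- function(community, degree_noise = 0, drop_unsampled = TRUE,
                    include_ibd = TRUE, ibd_min_cM = 8, seed = 1L) {
  ped <- community$pedigree
  ind <- ped$ind
  keep <- if (drop_unsampled) ind$sampled else rep(TRUE, nrow(ind))
  ids <- sort(ind$id[keep])

  if (is.matrix(degree_noise)) {
    M <- degree_noise
    if (!all(dim(M) == length(DEGREE_LEVELS))) {
      stop("confusion matrix must be ", length(DEGREE_LEVELS), "x",
           length(DEGREE_LEVELS))
    }
    if (any(abs(rowSums(M) - 1) > 1e-9)) {
      stop("confusion matrix rows must sum to 1")
    }
    off <- M; diag(off) <- 0
    adj <- row(M) - col(M)
    if (any(off[abs(adj) > 1] > 0)) {
      stop("confusion matrix must perturb adjacent degrees only")
    }
  } else {
    M <- degree_confusion_matrix(degree_noise)
  }

  truth <- expected_degree_table(ped, ids = ids)
  degrees <- truth
  with_seed(substream_seed(seed, "observe"), {
    if (nrow(degrees)) {
      from <- match(degrees$degree, DEGREE_LEVELS)
      to <- vapply(from, function(i) {
        sample.int(length(DEGREE_LEVELS), 1L, prob = M[i, ])
      }, integer(1))
      changed <- to != from
      degrees$degree <- DEGREE_LEVELS[to]
      degrees$first_degree_type[changed] <- "unknown"
      degrees$first_degree_type[degrees$degree != "1"] <- "unknown"
      degrees$source <- "observed"
    }
  })

  metadata <- ind[keep, , drop = FALSE]
  metadata$father <- NULL
  metadata$mother <- NULL
  metadata$generation <- NULL
  rownames(metadata) <- NULL

  ibd <- NULL
  if (include_ibd) {
    if (is.null(community$genomes)) {
      stop("include_ibd = TRUE requires genomes; run drop_genomes() first")
    }
    ibd <- ibd_table(community,
                     pairs = t(utils::combn(ids, 2L)),
                     min_len_cM = ibd_min_cM)
  }
  list(metadata = metadata, degrees = degrees, ibd = ibd, truth = truth)
}
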