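#' @keywords internal
"_PACKAGE"

## Age-at-death categories used for demographic profiling. Bins follow the
## anthropological convention: infants I 0-6, infants II 7-13, juveniles
## 14-17, young adults 18-25, young-middle adults 26-35, middle adults
## 36-50, older adults 50+.
AGE_CATEGORIES <- c("inf I", "inf II", "juv", "ya", "yma", "ma", "oa")
AGE_BREAKS <- c(0, 7, 14, 18, 26, 36, 51, Inf)

#' Age category for an age-at-death midpoint
#'
#' Maps an age in years to the seven-level anthropological age-at-death
#' scale (`inf I`, `inf II`, `juv`, `ya`, `yma`, `ma`, `oa`).
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of category labels; `NA` for `NA` input.
#' @export
age_category_of <- function(age) {
  out <- as.character(cut(age, breaks = AGE_BREAKS, labels = AGE_CATEGORIES,
                          right = FALSE, include.lowest = TRUE))
  out[is.na(age)] <- NA_character_
  out
}

## Canonical column set for the individuals table.
IND_COLUMNS <- c("id", "father", "mother", "sex", "sampled", "site",
                 "mt_hap", "y_hap", "age_low", "age_high", "age_category",
                 "anc_EastAsian", "anc_European", "anc_Steppe",
                 "status_items", "grave_x", "grave_y", "generation")

empty_individuals <- function() {
  data.frame(
    id = character(), father = character(), mother = character(),
    sex = character(), sampled = logical(), site = character(),
    mt_hap = character(), y_hap = character(),
    age_low = numeric(), age_high = numeric(), age_category = character(),
    anc_EastAsian = numeric(), anc_European = numeric(), anc_Steppe = numeric(),
    status_items = character(), grave_x = numeric(), grave_y = numeric(),
    generation = integer(),
    stringsAsFactors = FALSE
  )
}

complete_individuals <- function(df) {
  tmpl <- empty_individuals()
  for (cn in IND_COLUMNS) {
    if (!cn %in% names(df)) {
      df[[cn]] <- switch(class(tmpl[[cn]]),
        character = rep(NA_character_, nrow(df)),
        logical   = rep(NA, nrow(df)),
        numeric   = rep(NA_real_, nrow(df)),
        integer   = rep(NA_integer_, nrow(df))
      )
    }
  }
  if (all(is.na(df$sampled))) df$sampled <- rep(TRUE, nrow(df))
  df$sampled[is.na(df$sampled)] <- TRUE
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df[, IND_COLUMNS, drop = FALSE]
}

#' Construct a pedigree
#'
#' A pedigree is a parent-link directed acyclic graph over individuals,
#' sampled (buried on site) or latent (inferred, `sampled = FALSE`).  Each
#' individual has at most one mother (female) and one father (male).
#' Uniparental markers are constrained by transmission: children share
#' their mother's mtDNA haplogroup and sons their father's Y haplogroup
#' whenever both are known.
#'
#' @param individuals Data frame with at least an `id` column; recognised
#'   columns are `father`, `mother`, `sex` (`"male"`, `"female"`,
#'   `"unknown"`), `sampled`, `site`, `mt_hap`, `y_hap`, `age_low`,
#'   `age_high`, `age_category`, ancestry proportions `anc_EastAsian`,
#'   `anc_European`, `anc_Steppe`, `status_items` (comma-separated flags),
#'   `grave_x`, `grave_y`.  Missing columns are filled with `NA`;
#'   `sampled` defaults to `TRUE`.
#' @param validate If `TRUE` (default), structural invariants are checked
#'   and violations raise an error.
#' @return An object of class `pedigree`.
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("f", "m", "c"), sex = c("male", "female", "female"),
#'   father = c(NA, NA, "f"), mother = c(NA, NA, "m")
#' ))
#' kinship_coefficient(ped, "f", "c")
#' @export
pedigree <- function(individuals, validate = TRUE) {
  ind <- complete_individuals(as.data.frame(individuals))
  if (anyDuplicated(ind$id)) {
    stop("duplicate individual ids: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  }
  ind$sex[is.na(ind$sex)] <- "unknown"
  ped <- structure(list(ind = ind), class = "pedigree")
  if (validate) {
    viol <- validate_pedigree(ped)
    if (length(viol)) stop("invalid pedigree: ", paste(viol, collapse = "; "))
  }
  ped <- assign_generations(ped)
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  n <- nrow(x$ind)
  cat(sprintf("<pedigree> %d individuals (%d sampled, %d latent), %d parent links\n",
              n, sum(x$ind$sampled), sum(!x$ind$sampled),
              sum(!is.na(x$ind$father)) + sum(!is.na(x$ind$mother))))
  if (!all(is.na(x$ind$generation))) {
    cat(sprintf("  generations: %d\n", max(x$ind$generation, na.rm = TRUE)))
  }
  invisible(x)
}

#' Individuals table of a pedigree
#' @param ped A `pedigree`.
#' @return The individuals data frame.
#' @export
individuals <- function(ped) ped$ind

ped_index <- function(ped) stats::setNames(seq_len(nrow(ped$ind)), ped$ind$id)

#' Check pedigree structural invariants
#'
#' Verifies referential integrity of parent links, parental sexes,
#' acyclicity, and transmission of uniparental markers (mtDNA from the
#' mother to all children, Y haplogroup from the father to sons) wherever
#' both ends are known.  Also checks that `y_hap` is absent for females
#' and that ancestry proportions, when present, lie in \[0, 1\] and sum
#' to one.
#'
#' @param ped A `pedigree`.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_pedigree <- function(ped) {
  ind <- ped$ind
  viol <- character()
  idx <- ped_index(ped)
  bad_f <- !is.na(ind$father) & !(ind$father %in% ind$id)
  bad_m <- !is.na(ind$mother) & !(ind$mother %in% ind$id)
  if (any(bad_f)) viol <- c(viol, paste0("unknown father id for ", ind$id[bad_f]))
  if (any(bad_m)) viol <- c(viol, paste0("unknown mother id for ", ind$id[bad_m]))
  if (length(viol)) return(viol)

  fsex <- ind$sex[idx[ind$father]]
  msex <- ind$sex[idx[ind$mother]]
  if (any(!is.na(fsex) & fsex == "female")) {
    viol <- c(viol, paste0("father of ", ind$id[!is.na(fsex) & fsex == "female"],
                           " is female"))
  }
  if (any(!is.na(msex) & msex == "male")) {
    viol <- c(viol, paste0("mother of ", ind$id[!is.na(msex) & msex == "male"],
                           " is male"))
  }
  same <- !is.na(ind$father) & !is.na(ind$mother) & ind$father == ind$mother
  if (any(same)) viol <- c(viol, paste0("identical parents for ", ind$id[same]))

  if (is.null(topological_order(ped))) {
    viol <- c(viol, "cycle in parent links")
    return(viol)
  }

  mo_mt <- ind$mt_hap[idx[ind$mother]]
  bad_mt <- !is.na(mo_mt) & !is.na(ind$mt_hap) & mo_mt != ind$mt_hap
  if (any(bad_mt)) {
    viol <- c(viol, paste0("mtDNA of ", ind$id[bad_mt],
                           " differs from mother's"))
  }
  fa_y <- ind$y_hap[idx[ind$father]]
  bad_y <- ind$sex == "male" & !is.na(fa_y) & !is.na(ind$y_hap) & fa_y != ind$y_hap
  if (any(bad_y)) {
    viol <- c(viol, paste0("Y haplogroup of ", ind$id[bad_y],
                           " differs from father's"))
  }
  y_female <- ind$sex == "female" & !is.na(ind$y_hap)
  if (any(y_female)) {
    viol <- c(viol, paste0("female ", ind$id[y_female], " carries a Y haplogroup"))
  }

  anc <- as.matrix(ind[, c("anc_EastAsian", "anc_European", "anc_Steppe")])
  has_anc <- stats::complete.cases(anc)
  if (any(has_anc)) {
    a <- anc[has_anc, , drop = FALSE]
    if (any(a < -1e-9 | a > 1 + 1e-9)) {
      viol <- c(viol, "ancestry proportion outside [0, 1]")
    }
    if (any(abs(rowSums(a) - 1) > 1e-9)) {
      viol <- c(viol, "ancestry proportions do not sum to 1")
    }
  }
  viol
}

## Topological order of individuals (parents before children); NULL if cyclic.
topological_order <- function(ped) {
  ind <- ped$ind
  n <- nrow(ind)
  if (n == 0L) return(integer())
  idx <- ped_index(ped)
  fa <- idx[ind$father]
  mo <- idx[ind$mother]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) NULL else out
}

#' Assign generation layers
#'
#' Layers a pedigree by longest ancestral chain: an individual's
#' generation is one more than the maximum generation of its parents, and
#' founders sit one level below their earliest child (so that spouses who
#' married into the community are profiled with their reproductive
#' generation rather than at the top of the pedigree).  Levels are
#' 1-based and contiguous.
#'
#' @param ped A `pedigree`.
#' @return The pedigree with the `generation` column filled in.
#' @export
assign_generations <- function(ped) {
  ind <- ped$ind
  n <- nrow(ind)
  if (n == 0L) { ped$ind$generation <- integer(0); return(ped) }
  ord <- topological_order(ped)
  if (is.null(ord)) stop("cycle in parent links; cannot assign generations")
  idx <- ped_index(ped)
  gen <- rep(1L, n)
  fa <- idx[ind$father]; mo <- idx[ind$mother]
  for (i in ord) {
    pg <- c(gen[fa[i]], gen[mo[i]])
    pg <- pg[!is.na(c(fa[i], mo[i]))]
    if (length(pg)) gen[i] <- max(pg) + 1L
  }
  ## founders are lifted to just below their earliest child, keeping
  ## child = max(parents) + 1 satisfiable
  founder <- is.na(fa) & is.na(mo)
  for (i in which(founder)) {
    ch <- which((!is.na(fa) & fa == i) | (!is.na(mo) & mo == i))
    if (length(ch)) gen[i] <- max(gen[i], min(gen[ch]) - 1L)
  }
  ## compact to contiguous 1-based levels
  lev <- sort(unique(gen))
  gen <- match(gen, lev)
  ped$ind$generation <- as.integer(gen)
  ped
}

#' Restrict a pedigree to a set of individuals
#'
#' Keeps the given individuals and severs parent links pointing outside
#' the set.
#'
#' @param ped A `pedigree`.
#' @param ids Individual ids to keep.
#' @return A `pedigree` on the subset.
#' @export
restrict_pedigree <- function(ped, ids) {
  check_ids(ped, ids)
  ind <- ped$ind[ped$ind$id %in% ids, , drop = FALSE]
  ind$father[!ind$father %in% ids] <- NA_character_
  ind$mother[!ind$mother %in% ids] <- NA_character_
  ind$generation <- NULL
  pedigree(ind)
}

## all ancestors of an individual (excluding itself)
pedigree_ancestors <- function(ped, id) {
  anc <- character(0)
  queue <- id
  while (length(queue)) {
    q <- queue[1L]; queue <- queue[-1L]
    r <- ped$ind[match(q, ped$ind$id), ]
    for (p in c(r$father, r$mother)) {
      if (!is.na(p) && !(p %in% anc)) {
        anc <- c(anc, p); queue <- c(queue, p)
      }
    }
  }
  anc
}

## --- small mutation helpers used by the reconstruction engine ------------

add_individual <- function(ped, id, sex = "unknown", sampled = FALSE, ...) {
  stopifnot(!(id %in% ped$ind$id))
  row <- complete_individuals(data.frame(id = id, sex = sex,
                                         stringsAsFactors = FALSE))
  row$sampled <- sampled
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  ped$ind <- rbind(ped$ind, row[, IND_COLUMNS])
  ped
}

set_parent <- function(ped, child, parent, role = c("father", "mother")) {
  role <- match.arg(role)
  i <- match(child, ped$ind$id)
  stopifnot(!is.na(i), parent %in% ped$ind$id)
  ped$ind[[role]][i] <- parent
  ped
}

## Replace all references to `from` by `to` and drop `from` (used when two
## latent parents are discovered to be the same person).
merge_individuals <- function(ped, from, to) {
  stopifnot(from %in% ped$ind$id, to %in% ped$ind$id, from != to)
  ind <- ped$ind
  ind$father[!is.na(ind$father) & ind$father == from] <- to
  ind$mother[!is.na(ind$mother) & ind$mother == from] <- to
  i <- match(from, ind$id); j <- match(to, ind$id)
  ## carry over any information the kept record lacks
  for (cn in setdiff(IND_COLUMNS, c("id"))) {
    if (is.na(ind[[cn]][j]) && !is.na(ind[[cn]][i])) ind[[cn]][j] <- ind[[cn]][i]
  }
  ped$ind <- ind[-i, , drop = FALSE]
  ped
}
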