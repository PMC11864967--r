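#' Kinship matrix of a pedigree
#'
#' Computes Wright's coancestry (kinship) coefficient between every pair
#' of pedigree members by the standard tabular recursion:
#' \eqn{\varphi(i,i) = (1 + F_i)/2} and, for \eqn{i} with parents
#' \eqn{f, m}, \eqn{\varphi(i,j) = (\varphi(f,j) + \varphi(m,j))/2} for
#' any \eqn{j} that is not a descendant of \eqn{i}; missing parents
#' contribute zero.
#'
#' @param ped A `pedigree`.
#' @return Symmetric numeric matrix with individual ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  ind <- ped$ind
  n <- nrow(ind)
  K <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  if (n == 0L) return(K)
  ord <- topological_order(ped)
  if (is.null(ord)) stop("cycle in parent links")
  idx <- ped_index(ped)
  fa <- idx[ind$father]; mo <- idx[ind$mother]
  done <- integer(0)
  for (i in ord) {
    kf <- if (!is.na(fa[i])) K[fa[i], done] else numeric(length(done))
    km <- if (!is.na(mo[i])) K[mo[i], done] else numeric(length(done))
    if (length(done)) {
      K[i, done] <- K[done, i] <- 0.5 * (kf + km)
    }
    Fi <- if (!is.na(fa[i]) && !is.na(mo[i])) K[fa[i], mo[i]] else 0
    K[i, i] <- 0.5 * (1 + Fi)
    done <- c(done, i)
  }
  K
}

check_ids <- function(ped, ids) {
  missing <- setdiff(ids, ped$ind$id)
  if (length(missing)) {
    stop("unknown individual id(s): ", paste(missing, collapse = ", "))
  }
}

#' Kinship coefficient between two individuals
#'
#' The probability that two alleles drawn at random, one from each
#' individual, are identical by descent given the pedigree.  Parent and
#' offspring (outbred) have \eqn{\varphi = 1/4}; full first cousins
#' \eqn{1/16}; founders 0.
#'
#' @param ped A `pedigree`.
#' @param i,j Individual ids.
#' @return Kinship coefficient in \[0, 1\].
#' @export
kinship_coefficient <- function(ped, i, j) {
  check_ids(ped, c(i, j))
  K <- kinship_matrix(ped)
  unname(K[i, j])
}

#' Inbreeding coefficient
#'
#' \eqn{F_i} is the kinship coefficient of the individual's parents (zero
#' when either parent is missing): the expected autozygous fraction of
#' the genome, observable as runs of homozygosity.
#'
#' @inheritParams kinship_coefficient
#' @return Inbreeding coefficient in \[0, 1\].
#' @export
inbreeding_coefficient <- function(ped, i) {
  check_ids(ped, i)
  row <- ped$ind[match(i, ped$ind$id), ]
  if (is.na(row$father) || is.na(row$mother)) return(0)
  kinship_coefficient(ped, row$father, row$mother)
}

#' Degree bins on the kinship scale
#'
#' Relatedness degree \eqn{d} corresponds to an expected kinship of
#' \eqn{2^{-(d+1)}}.  Bins are cut halfway between neighbouring degrees
#' on the log2 scale, i.e. at \eqn{2^{-(d+1.5)}}; a kinship exactly on a
#' boundary is assigned to the closer-relative (lower-degree) bin.
#' Degrees run from `"identical"` (twin / duplicate, \eqn{\varphi \ge
#' 2^{-1.5}}) through `"1"` ... `"6"` to `"unrelated"`.
#'
#' @param max_degree Largest classified degree (default 6).
#' @return Object of class `degree_bins`: data frame of degree labels and
#'   lower kinship thresholds (inclusive), strictly decreasing.
#' @export
degree_bins <- function(max_degree = 6L) {
  d <- 0:max_degree
  bins <- data.frame(
    degree = c("identical", as.character(seq_len(max_degree))),
    lower = 2^-(d + 1.5),
    centre = 2^-(d + 1),
    stringsAsFactors = FALSE
  )
  class(bins) <- c("degree_bins", "data.frame")
  bins
}

#' Classify a kinship coefficient into a relatedness degree
#'
#' @param phi Numeric vector of kinship coefficients.
#' @param bins Bins from [degree_bins()].
#' @return Character vector of degree labels (`"identical"`, `"1"` ...
#'   `"6"`, `"unrelated"`); boundary values go to the closer-relative bin.
#' @export
degree_of_kinship <- function(phi, bins = degree_bins()) {
  out <- rep("unrelated", length(phi))
  ## assign from the loosest bin inward so the final label is the
  ## closest-relative bin whose (inclusive) threshold the value reaches
  for (k in rev(seq_len(nrow(bins)))) {
    out[phi >= bins$lower[k]] <- bins$degree[k]
  }
  out
}

#' Numeric degree scale used in consistency scoring
#'
#' `"identical"` maps to 0, `"1"`..`"6"` to 1..6 and `"unrelated"` to 7
#' (a proxy that keeps far-degree misestimates bounded).
#'
#' @param degree Character vector of degree labels.
#' @return Integer vector.
#' @export
degree_numeric <- function(degree) {
  out <- suppressWarnings(as.integer(degree))
  out[degree == "identical"] <- 0L
  out[degree == "unrelated"] <- 7L
  out
}

#' Expected relatedness degree of a pair under a pedigree
#'
#' Maps the pedigree kinship coefficient through [degree_bins()] and, for
#' first-degree pairs, distinguishes parent-offspring from siblings by
#' graph structure.
#'
#' @inheritParams kinship_coefficient
#' @param bins Bins from [degree_bins()].
#' @param K Optional precomputed [kinship_matrix()] (avoids recomputation
#'   in loops).
#' @return List with `degree` (label) and `first_degree_type`
#'   (`"parent_offspring"`, `"sibling"` or `"unknown"`).
#' @export
expected_degree <- function(ped, i, j, bins = degree_bins(), K = NULL) {
  if (identical(i, j)) stop("expected_degree requires two distinct individuals")
  check_ids(ped, c(i, j))
  phi <- if (is.null(K)) kinship_coefficient(ped, i, j) else unname(K[i, j])
  deg <- degree_of_kinship(phi, bins)
  type <- "unknown"
  if (deg == "1") {
    ri <- ped$ind[match(i, ped$ind$id), ]
    rj <- ped$ind[match(j, ped$ind$id), ]
    po <- (!is.na(ri$father) && ri$father == j) ||
      (!is.na(ri$mother) && ri$mother == j) ||
      (!is.na(rj$father) && rj$father == i) ||
      (!is.na(rj$mother) && rj$mother == i)
    sib <- !po && !is.na(ri$father) && !is.na(rj$father) &&
      !is.na(ri$mother) && !is.na(rj$mother) &&
      ri$father == rj$father && ri$mother == rj$mother
    type <- if (po) "parent_offspring" else if (sib) "sibling" else "unknown"
  }
  list(degree = deg, first_degree_type = type)
}

#' Expected degrees for all pairs of a pedigree
#'
#' Vectorised companion to [expected_degree()]: returns one row per
#' unordered pair of (by default, sampled) pedigree members, in canonical
#' pair order.
#'
#' @param ped A `pedigree`.
#' @param ids Individuals to include (default: all sampled members).
#' @param bins Bins from [degree_bins()].
#' @return Data frame of [degree_record]s: `id_a`, `id_b`, `degree`,
#'   `first_degree_type`, `source`.
#' @export
expected_degree_table <- function(ped, ids = NULL, bins = degree_bins()) {
  ind <- ped$ind
  if (is.null(ids)) ids <- ind$id[ind$sampled]
  check_ids(ped, ids)
  if (length(ids) < 2L) return(empty_degree_records())
  K <- kinship_matrix(ped)
  pr <- utils::combn(sort(ids), 2L)
  phi <- K[cbind(pr[1L, ], pr[2L, ])]
  deg <- degree_of_kinship(phi, bins)
  idx <- match(ids, ind$id)
  fa <- stats::setNames(ind$father[idx], ids)
  mo <- stats::setNames(ind$mother[idx], ids)
  a <- pr[1L, ]; b <- pr[2L, ]
  po <- (!is.na(fa[a]) & fa[a] == b) | (!is.na(mo[a]) & mo[a] == b) |
    (!is.na(fa[b]) & fa[b] == a) | (!is.na(mo[b]) & mo[b] == a)
  sib <- !po & !is.na(fa[a]) & !is.na(fa[b]) & !is.na(mo[a]) & !is.na(mo[b]) &
    fa[a] == fa[b] & mo[a] == mo[b]
  type <- ifelse(deg != "1", "unknown",
                 ifelse(po, "parent_offspring",
                        ifelse(sib, "sibling", "unknown")))
  data.frame(id_a = a, id_b = b, degree = deg, first_degree_type = type,
             source = "pedigree", row.names = NULL, stringsAsFactors = FALSE)
}
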