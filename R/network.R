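## IBD networks and dyad-covariate models.
##
## With only dyadic-independent covariate terms, the exponential-family
## network model factorises over dyads into independent Bernoulli tie
## variables whose log-odds are linear in the covariates; the fit below
## maximises that likelihood directly (iteratively reweighted least
## squares) and reports fold-changes exp(coefficient), Wald Z-tests and
## AIC.  Site-level continuous networks are tested against covariate
## matrices with QAP label permutations.

#' Build the binary IBD network over sampled individuals
#'
#' The dyad universe is the complete graph on sampled individuals with
#' usable covariates; non-tied pairs are explicit zeros.  Ties follow
#' either the long-segment relatedness rule (more than
#' `min_long_segments` segments over `long_segment_cM`; see
#' [classify_ibd_relatedness()]) or the `sum_threshold` rule (any
#' segment longer than `network_segment_cM`, default 16).
#'
#' @param ibd IBD record data frame.
#' @param metadata Individual metadata.
#' @param rule `"long_segments"` or `"sum_threshold"`.
#' @param config An [analysis_config()].
#' @param exclude Optional ids to drop from the dyad universe (for
#'   example merged twin units).
#' @return Data frame of class `ibd_network`: `id_a`, `id_b`, `tie`,
#'   `sex_pairing` (`FF`/`FM`/`MM`), `same_site`, `status_count`
#'   (0, 1 or 2 carriers of a configured prestige object).  Dyads with
#'   missing covariates are excluded; their count is in
#'   `attr(, "n_excluded")`.
#' @export
build_binary_network <- function(ibd, metadata,
                                 rule = c("long_segments", "sum_threshold"),
                                 config = analysis_config(),
                                 exclude = NULL) {
  rule <- match.arg(rule)
  ind <- complete_individuals(metadata)
  ind <- ind[!(ind$id %in% exclude), , drop = FALSE]
  ids <- sort(ind$id)
  if (length(ids) < 2L) stop("need at least two individuals")
  pr <- utils::combn(ids, 2L)
  net <- data.frame(id_a = pr[1L, ], id_b = pr[2L, ],
                    stringsAsFactors = FALSE)

  m <- match(paste(net$id_a, net$id_b),
             paste(ibd$id_a, ibd$id_b))
  if (rule == "long_segments") {
    gt20 <- ifelse(is.na(m), 0L, ibd$n_segments_gt20[m])
    net$tie <- gt20 > config$min_long_segments
  } else {
    longest <- ifelse(is.na(m), 0, ibd$longest_cM[m])
    net$tie <- longest > config$network_segment_cM
  }

  ia <- match(net$id_a, ind$id); ib <- match(net$id_b, ind$id)
  sexes <- cbind(ind$sex[ia], ind$sex[ib])
  nf <- rowSums(sexes == "female")
  nm <- rowSums(sexes == "male")
  net$sex_pairing <- ifelse(nf == 2L, "FF", ifelse(nm == 2L, "MM", "FM"))
  net$sex_pairing[nf + nm < 2L] <- NA_character_
  net$same_site <- ind$site[ia] == ind$site[ib]
  has_status <- function(items) {
    !is.na(items) & vapply(strsplit(ifelse(is.na(items), "", items), ","),
                           function(x) any(x %in% config$status_item_set),
                           logical(1))
  }
  net$status_count <- has_status(ind$status_items[ia]) +
    has_status(ind$status_items[ib])

  keep <- !is.na(net$sex_pairing) & !is.na(net$same_site)
  out <- net[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "rule") <- rule
  class(out) <- c("ibd_network", "data.frame")
  out
}

ergm_design <- function(network, terms) {
  n <- nrow(network)
  X <- matrix(1, n, 1, dimnames = list(NULL, "edges"))
  for (tm in terms) {
    if (tm == "sex_pairing") {
      X <- cbind(X, sex_pairing.FM = as.numeric(network$sex_pairing == "FM"),
                 sex_pairing.MM = as.numeric(network$sex_pairing == "MM"))
    } else if (tm == "status_count") {
      X <- cbind(X, status_count.1 = as.numeric(network$status_count == 1L),
                 status_count.2 = as.numeric(network$status_count == 2L))
    } else if (tm == "same_site") {
      X <- cbind(X, same_site = as.numeric(network$same_site))
    } else if (tm %in% names(network)) {
      v <- network[[tm]]
      if (is.logical(v)) v <- as.numeric(v)
      if (!is.numeric(v)) stop("term '", tm, "' is not numeric or logical")
      X <- cbind(X, stats::setNames(data.frame(v), tm)[[1]])
      colnames(X)[ncol(X)] <- tm
    } else {
      stop("unknown model term: ", tm)
    }
  }
  X
}

#' Fit a dyad-covariate exponential-family network model
#'
#' Maximum-likelihood fit of the Bernoulli dyad model: the tie log-odds
#' are linear in the dyadic covariates (the exponential-family network
#' model restricted to dyadic independence).  Reference categories are
#' `FF` for `sex_pairing` and `0` for `status_count`; fold-changes are
#' exp(coefficient).  Z-tests are two-sided Wald tests; a Bonferroni
#' column is included for transparency, with no correction applied to
#' the headline p-values.  Separation (a covariate level whose dyads
#' are all tied or all untied) is flagged and the coefficient reported
#' as a boundary estimate with a warning; aliased design columns are
#' dropped with a notice.
#'
#' @param network An `ibd_network` (or data frame with a logical `tie`
#'   column and covariates).
#' @param terms Character vector of covariate terms (default
#'   `sex_pairing`; recognised: `sex_pairing`, `status_count`,
#'   `same_site`, or any numeric/logical column).
#' @param max_iter,tol IRLS controls.
#' @return Object of class `ergm_fit`: `coefficients` data frame
#'   (`term`, `estimate`, `se`, `z`, `p`, `p_bonferroni`, `fold`),
#'   `loglik`, `aic`, `n_dyads`, `terms`, `reference`, `dropped`,
#'   `separation`.
#' @export
fit_dyadic_ergm <- function(network, terms = "sex_pairing",
                            max_iter = 100L, tol = 1e-10) {
  y <- as.numeric(network$tie)
  X <- ergm_design(network, terms)

  ## drop aliased columns
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, sort(keep), drop = FALSE]
  }
  ## drop constant-zero dummies (level absent from the data)
  zero <- colnames(X)[colSums(abs(X)) == 0]
  if (length(zero)) {
    dropped <- c(dropped, zero)
    X <- X[, setdiff(colnames(X), zero), drop = FALSE]
  }

  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    w <- pmax(w, 1e-12)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - p)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  separation <- any(abs(beta) > 12)
  if (separation) {
    warning("separation detected: a covariate level is perfectly ",
            "predictive; boundary estimate reported")
  }
  XtWX <- crossprod(X, X * pmax(p * (1 - p), 1e-12))
  se <- sqrt(diag(solve(XtWX)))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  k <- length(beta)
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se, z = z,
                      p = pv, p_bonferroni = pmin(1, pv * max(1, k - 1)),
                      fold = exp(beta), row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = ll, aic = 2 * k - 2 * ll,
                 n_dyads = length(y), terms = terms,
                 reference = "FF sex pairing; status_count 0",
                 dropped = dropped, separation = separation),
            class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("<ergm_fit> dyad-independent model on %d dyads; terms: %s\n",
              x$n_dyads, paste(x$terms, collapse = " + ")))
  cat(sprintf("  logLik %.2f, AIC %.2f (reference: %s)\n",
              x$loglik, x$aic, x$reference))
  print(within(x$coefficients, {
    estimate <- round(estimate, 4); se <- round(se, 4); z <- round(z, 2)
    p <- signif(p, 3); p_bonferroni <- signif(p_bonferroni, 3)
    fold <- round(fold, 3)
  }))
  if (length(x$dropped)) cat("  dropped terms:",
                             paste(x$dropped, collapse = ", "), "\n")
  if (x$separation) cat("  WARNING: separation; boundary estimate\n")
  invisible(x)
}

#' Select the minimum-AIC dyadic model
#'
#' Fits every candidate additive term set and returns the fit with the
#' smallest AIC; ties are broken toward fewer terms.
#'
#' @param network An `ibd_network`.
#' @param candidates List of character vectors of terms.
#' @return The best `ergm_fit`, with the AIC table in
#'   `attr(, "aic_table")`.
#' @export
select_model <- function(network, candidates) {
  if (!length(candidates)) stop("at least one candidate term set required")
  fits <- lapply(candidates, function(tm) fit_dyadic_ergm(network, tm))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  sizes <- vapply(candidates, length, integer(1))
  best <- order(aics, sizes)[1L]
  out <- fits[[best]]
  attr(out, "aic_table") <- data.frame(
    terms = vapply(candidates, paste, character(1), collapse = "+"),
    k = sizes, aic = aics, selected = seq_along(fits) == best,
    stringsAsFactors = FALSE)
  out
}

#' Build the site-level IBD sharing network
#'
#' Edge weight between two sites is the mean total IBD sharing (cM) over
#' all cross-site pairs, zero-sharing pairs included.  Node attributes
#' carry mean ancestry proportions and mean coordinates.  Sites with
#' fewer than two individuals are retained with a note.
#'
#' @param ibd IBD record data frame.
#' @param metadata Individual metadata with `site` labels.
#' @return List with `sites` (node table), `edges` (site pairs with
#'   `weight`), `W` (symmetric weight matrix) and `notes`.
#' @export
build_site_network <- function(ibd, metadata) {
  ind <- complete_individuals(metadata)
  ind <- ind[!is.na(ind$site), , drop = FALSE]
  sites <- sort(unique(ind$site))
  notes <- character()
  n_by_site <- table(ind$site)
  small <- names(n_by_site)[n_by_site < 2]
  if (length(small)) {
    notes <- c(notes, paste0("site ", small, " has fewer than 2 individuals"))
  }
  tot <- stats::setNames(ibd$total_cM, paste(ibd$id_a, ibd$id_b))
  W <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  edges <- list()
  for (i in seq_along(sites)) {
    for (j in seq_along(sites)) {
      if (j <= i) next
      a_ids <- ind$id[ind$site == sites[i]]
      b_ids <- ind$id[ind$site == sites[j]]
      pairs <- expand.grid(a = a_ids, b = b_ids, stringsAsFactors = FALSE)
      key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
      v <- tot[key]
      v[is.na(v)] <- 0
      w <- mean(v)
      W[i, j] <- W[j, i] <- w
      edges[[length(edges) + 1L]] <- data.frame(
        site_a = sites[i], site_b = sites[j], weight = w,
        n_pairs = nrow(pairs), stringsAsFactors = FALSE)
    }
  }
  anc <- do.call(rbind, lapply(sites, function(s) {
    sub <- ind[ind$site == s, ]
    data.frame(site = s, n = nrow(sub),
               anc_EastAsian = mean(sub$anc_EastAsian, na.rm = TRUE),
               anc_European = mean(sub$anc_European, na.rm = TRUE),
               anc_Steppe = mean(sub$anc_Steppe, na.rm = TRUE),
               x = mean(sub$grave_x, na.rm = TRUE),
               y = mean(sub$grave_y, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(sites = anc,
       edges = if (length(edges)) do.call(rbind, edges) else NULL,
       W = W, notes = notes)
}

#' QAP permutation test for a site-level covariate
#'
#' Correlates the off-diagonal entries of the site weight matrix with a
#' covariate matrix (geographic distance, ancestry dissimilarity, ...)
#' and builds the null by jointly permuting the node labels of the
#' covariate matrix.  The two-sided p-value uses the add-one correction
#' `(1 + #{|r*| >= |r|}) / (n_permutations + 1)`.
#'
#' @param W Symmetric weight matrix.
#' @param C Symmetric covariate matrix in the same node order.
#' @param n_permutations Number of label permutations.
#' @param seed Seed for the permutation draws.
#' @return List with `statistic` (Pearson r), `p_value`,
#'   `n_permutations`, and `note` (`"constant covariate"` with `NULL`
#'   statistic when the covariate does not vary).
#' @export
site_covariate_test <- function(W, C, n_permutations = 999L, seed = 1L) {
  stopifnot(is.matrix(W), is.matrix(C), all(dim(W) == dim(C)))
  n <- nrow(W)
  lw <- W[lower.tri(W)]
  lc <- C[lower.tri(C)]
  if (stats::sd(lc) == 0 || stats::sd(lw) == 0) {
    return(list(statistic = NULL, p_value = NULL,
                n_permutations = n_permutations,
                note = "constant covariate"))
  }
  r_obs <- stats::cor(lw, lc)
  with_seed(substream_seed(seed, "qap"), {
    r_perm <- vapply(seq_len(n_permutations), function(b) {
      idx <- sample.int(n)
      Cp <- C[idx, idx]
      stats::cor(lw, Cp[lower.tri(Cp)])
    }, numeric(1))
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_permutations + 1)
  list(statistic = r_obs, p_value = p, n_permutations = n_permutations,
       note = NULL)
}

#' Within- and between-site tie rates by sex pairing
#'
#' Rate table (within/between site by FF/FM/MM) with exact binomial
#' confidence intervals; empty cells report a `NULL` rate with count 0.
#'
#' @param network An `ibd_network` with the `same_site` covariate.
#' @return Data frame with `scope`, `sex_pairing`, `n_dyads`, `n_ties`,
#'   `rate`, `ci_low`, `ci_high`.
#' @export
sexed_between_site_summary <- function(network) {
  out <- list()
  for (scope in c("within", "between")) {
    sel0 <- if (scope == "within") network$same_site else !network$same_site
    for (sp in c("FF", "FM", "MM")) {
      sel <- sel0 & network$sex_pairing == sp
      n <- sum(sel); t <- sum(network$tie[sel])
      if (n > 0) {
        ci <- stats::binom.test(t, n)$conf.int
        out[[length(out) + 1L]] <- data.frame(
          scope = scope, sex_pairing = sp, n_dyads = n, n_ties = t,
          rate = t / n, ci_low = ci[1], ci_high = ci[2],
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          scope = scope, sex_pairing = sp, n_dyads = 0L, n_ties = 0L,
          rate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Write a binary network as edge-list CSV and GraphML
#'
#' @param network An `ibd_network`.
#' @param metadata Individual metadata for node attributes.
#' @param csv_path,graphml_path Output paths (`NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_network <- function(network, metadata, csv_path = NULL,
                          graphml_path = NULL) {
  written <- list()
  ties <- network[network$tie, , drop = FALSE]
  if (!is.null(csv_path)) {
    utils::write.csv(ties, csv_path, row.names = FALSE)
    written$csv <- csv_path
  }
  if (!is.null(graphml_path)) {
    ind <- complete_individuals(metadata)
    ids <- sort(unique(c(network$id_a, network$id_b)))
    vatt <- ind[match(ids, ind$id), c("id", "sex", "site", "status_items")]
    vatt$status_items[is.na(vatt$status_items)] <- ""
    names(vatt)[1] <- "name"
    g <- igraph::graph_from_data_frame(ties[, c("id_a", "id_b")],
                                       directed = FALSE, vertices = vatt)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written$graphml <- graphml_path
  }
  invisible(written)
}
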