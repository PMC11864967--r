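## Stepwise pedigree reconstruction from pairwise relatedness degrees.
##
## The procedure mirrors how kinship analysts assemble burial-community
## pedigrees: (1) first-degree scaffold — sibling sets first, then
## parent-offspring links oriented by age at death, mtDNA and sex;
## (2) latent (unsampled) parents added wherever sibships lack them;
## (3) second-degree pairs classified as half-sibling, avuncular or
## grandparent-grandchild under the sibling-equality principle, age
## feasibility, haplogroup consistency and an IBD segment-count
## discriminant; (4) greedy consistency-scored assembly with
## backtracking, recording alternatives.

## ---------------------------------------------------------------------
## scoring

#' Consistency score of a pedigree against observed degrees
#'
#' Sum over observed pairs of minus the absolute difference between the
#' expected degree under the pedigree and the observed degree, with
#' `unrelated` treated as degree 7 and differences capped at 3 so that
#' far-degree misestimates cannot dominate.  Higher is better; a
#' pedigree explaining every record exactly scores 0.
#'
#' @param ped A `pedigree`.
#' @param degrees Degree-record data frame.
#' @param K Optional precomputed kinship matrix.
#' @return Single numeric score (<= 0).
#' @export
score_pedigree <- function(ped, degrees, K = NULL) {
  if (!nrow(degrees)) return(0)
  if (is.null(K)) K <- kinship_matrix(ped)
  ids <- rownames(K)
  a <- match(degrees$id_a, ids)
  b <- match(degrees$id_b, ids)
  phi <- rep(0, nrow(degrees))
  ok <- !is.na(a) & !is.na(b)
  phi[ok] <- K[cbind(a[ok], b[ok])]
  exp_num <- degree_numeric(degree_of_kinship(phi))
  obs_num <- degree_numeric(degrees$degree)
  -sum(pmin(3L, abs(exp_num - obs_num)))
}

## ---------------------------------------------------------------------
## step 1: first-degree scaffold

#' Build the first-degree scaffold
#'
#' Connects siblings first (transitive closure of sibling-typed
#' first-degree edges, conflicts flagged), then orients
#' parent-offspring edges: an individual linked parent-offspring to
#' every member of a sibship of two or more is a parent of that sibship;
#' remaining edges are oriented by age-at-death ordering (an individual
#' who died below the minimum reproductive age cannot be a parent; when
#' intervals are disjoint the elder is the parent), by mtDNA match for
#' mother identification, and by sex for the parental slot.
#' Unresolvable orientations are deferred to the scoring stage.
#'
#' @param degrees Degree-record data frame (canonical pairs).
#' @param metadata Individual metadata (see [read_metadata()]).
#' @param config An [analysis_config()].
#' @param ibd Optional IBD record data frame; pairs labelled `identical`
#'   are merged into twin units only when their IBD total carries the
#'   duplicate signature (above `config$twin_total_cM`); otherwise the
#'   label is treated as a first-degree record of unknown type, since a
#'   one-step classification error is far likelier than a twin.
#' @return A scaffold: list with `ped`, `sibships`, `deferred`
#'   (unoriented first-degree edges), `conflicts`, `twin_units`, `log`.
#' @export
build_first_degree_scaffold <- function(degrees, metadata,
                                        config = analysis_config(),
                                        ibd = NULL) {
  metadata <- complete_individuals(metadata)
  missing <- setdiff(unique(c(degrees$id_a, degrees$id_b)), metadata$id)
  if (length(missing)) {
    stop("degree table references ids absent from metadata: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  log <- character()
  conflicts <- character()

  ## twin units: merged into one node only with the duplicate IBD
  ## signature; otherwise demoted to an untyped first-degree record
  ibd_tot <- NULL
  if (!is.null(ibd) && nrow(ibd)) {
    ibd_tot <- stats::setNames(ibd$total_cM, paste(ibd$id_a, ibd$id_b))
  }
  twins <- degrees[degrees$degree == "identical", , drop = FALSE]
  twin_units <- list()
  drop_ids <- character()
  for (k in seq_len(nrow(twins))) {
    keep <- min(twins$id_a[k], twins$id_b[k])
    drop <- max(twins$id_a[k], twins$id_b[k])
    tot <- if (is.null(ibd_tot)) NA_real_ else ibd_tot[paste(keep, drop)]
    if (!is.na(tot) && tot > config$twin_total_cM) {
      twin_units[[keep]] <- sort(unique(c(twin_units[[keep]], keep, drop)))
      drop_ids <- c(drop_ids, drop)
      log <- c(log, sprintf("twin unit: %s merged into %s (IBD %.0f cM)",
                            drop, keep, tot))
    } else {
      sel <- degrees$id_a == keep & degrees$id_b == drop
      degrees$degree[sel] <- "1"
      degrees$first_degree_type[sel] <- "unknown"
      log <- c(log, sprintf(
        "identical label for %s-%s lacks duplicate IBD; treated as untyped first degree",
        keep, drop))
    }
  }
  if (length(drop_ids)) {
    metadata <- metadata[!metadata$id %in% drop_ids, , drop = FALSE]
    degrees <- degrees[!degrees$id_a %in% drop_ids &
                         !degrees$id_b %in% drop_ids, , drop = FALSE]
  }

  ped <- pedigree(metadata)
  deg1 <- degrees[degrees$degree == "1", , drop = FALSE]
  sib_e <- deg1[deg1$first_degree_type == "sibling", , drop = FALSE]
  po_e <- deg1[deg1$first_degree_type == "parent_offspring", , drop = FALSE]
  untyped_e <- deg1[deg1$first_degree_type == "unknown", , drop = FALSE]

  ## sibships: connected components of the sibling graph
  sibships <- list()
  if (nrow(sib_e)) {
    g <- igraph::graph_from_data_frame(sib_e[, c("id_a", "id_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)$membership
    sibships <- unname(split(names(comp), comp))
    sibships <- lapply(sibships, sort)
    ## transitivity check: flag missing within-sibship edges
    key <- paste(sib_e$id_a, sib_e$id_b)
    for (S in sibships) {
      if (length(S) < 3L) next
      pr <- utils::combn(S, 2L)
      miss <- !(paste(pr[1L, ], pr[2L, ]) %in% key)
      if (any(miss)) {
        conflicts <- c(conflicts, sprintf(
          "sibship {%s}: sibling edge %s-%s missing (transitivity enforced)",
          paste(S, collapse = ","), pr[1L, miss], pr[2L, miss]))
      }
    }
  }

  ## structural parents: an individual parent-offspring linked to (a
  ## noise-tolerant majority of) a sibship of size >= 2, and observed at
  ## degree <= 2 to every member, is its parent
  po_key <- paste(po_e$id_a, po_e$id_b)
  has_po <- function(x, y) {
    paste(min(x, y), max(x, y)) %in% po_key
  }
  obs_deg_num <- stats::setNames(degree_numeric(degrees$degree),
                                 paste(degrees$id_a, degrees$id_b))
  obs_between <- function(x, y) {
    v <- obs_deg_num[paste(min(x, y), max(x, y))]
    if (is.na(v)) 7L else v
  }
  assigned_po <- logical(nrow(po_e))
  for (S in sibships) {
    if (length(S) < 2L) next
    touching <- unique(c(po_e$id_a[po_e$id_b %in% S],
                         po_e$id_b[po_e$id_a %in% S]))
    touching <- setdiff(touching, S)
    parents <- touching[vapply(touching, function(p) {
      n_po <- sum(vapply(S, function(c) has_po(p, c), logical(1)))
      close_all <- all(vapply(S, function(c) obs_between(p, c) <= 2L,
                              logical(1)))
      ## at least two typed edges: a child of one member has only one,
      ## so the majority rule cannot mistake offspring for parents
      n_po >= max(2L, ceiling(length(S) / 2)) && close_all
    }, logical(1))]
    for (p in parents) {
      sexp <- ped$ind$sex[match(p, ped$ind$id)]
      role <- switch(sexp, male = "father", female = "mother", NA_character_)
      if (is.na(role)) {
        conflicts <- c(conflicts,
                       sprintf("parent %s of sibship {%s} has unknown sex",
                               p, paste(S, collapse = ",")))
        next
      }
      taken <- unique(stats::na.omit(ped$ind[[role]][match(S, ped$ind$id)]))
      if (length(taken) && any(taken != p)) {
        conflicts <- c(conflicts, sprintf(
          "sibship {%s} has competing %ss %s and %s; keeping first",
          paste(S, collapse = ","), role, taken[1], p))
        next
      }
      ## cycle guard: no member of S may already be an ancestor of p
      if (any(S %in% pedigree_ancestors(ped, p))) {
        conflicts <- c(conflicts, sprintf(
          "parent %s of sibship {%s} would create a cycle; suspended",
          p, paste(S, collapse = ",")))
        next
      }
      for (c in S) ped <- set_parent(ped, c, p, role)
      log <- c(log, sprintf("%s assigned as %s of sibship {%s}",
                            p, role, paste(S, collapse = ",")))
      for (c in S) assigned_po[po_e$id_a == min(p, c) &
                                 po_e$id_b == max(p, c)] <- TRUE
    }
  }

  ## orientation of the remaining parent-offspring edges
  pend <- po_e[!assigned_po, c("id_a", "id_b"), drop = FALSE]
  res <- orient_po_edges(ped, pend, degrees, config)
  ped <- res$ped
  log <- c(log, res$log)
  conflicts <- c(conflicts, res$conflicts)

  structure(list(ped = ped, sibships = sibships, deferred = rbind(
    res$deferred,
    stats::setNames(untyped_e[, c("id_a", "id_b"), drop = FALSE],
                    c("id_a", "id_b"))),
    conflicts = conflicts, twin_units = twin_units,
    degrees = degrees, config = config, log = log,
    latent_counter = 0L), class = "kin_scaffold")
}

## orient parent-offspring edges by hard rules, then by local
## consistency score; unresolved edges are returned as deferred
orient_po_edges <- function(ped, edges, degrees, config) {
  log <- character(); conflicts <- character()
  deferred <- edges[0, , drop = FALSE]
  if (!nrow(edges)) {
    return(list(ped = ped, deferred = deferred, log = log,
                conflicts = conflicts))
  }
  min_age <- config$min_parent_age

  can_parent <- function(p, c) {
    ## hard feasibility of "p is parent of c"
    rp <- ped$ind[match(p, ped$ind$id), ]
    rc <- ped$ind[match(c, ped$ind$id), ]
    if (!is.na(rp$age_high) && rp$age_high < min_age) return(FALSE)
    if (rp$sex == "female" && !is.na(rp$mt_hap) && !is.na(rc$mt_hap) &&
        rp$mt_hap != rc$mt_hap) return(FALSE)
    if (rp$sex == "male" && rc$sex == "male" && !is.na(rp$y_hap) &&
        !is.na(rc$y_hap) && rp$y_hap != rc$y_hap) return(FALSE)
    role <- if (rp$sex == "male") "father" else
      if (rp$sex == "female") "mother" else return(FALSE)
    cur <- rc[[role]]
    if (!is.na(cur) && cur != p) return(FALSE)
    ## cycle guard: c must not already be an ancestor of p
    !(c %in% pedigree_ancestors(ped, p))
  }
  apply_link <- function(p, c) {
    role <- if (ped$ind$sex[match(p, ped$ind$id)] == "male") "father" else "mother"
    set_parent(ped, c, p, role)
  }

  ## couple-child triangles: if x has parent-offspring edges to both a and
  ## b while a and b are observed as more distant than second degree,
  ## neither can be x's child or grandparent through x, so both are
  ## parents of x (requires opposite sexes)
  obs_num <- stats::setNames(degree_numeric(degrees$degree),
                             paste(degrees$id_a, degrees$id_b))
  forced_parents <- list()
  all_ids <- unique(c(edges$id_a, edges$id_b))
  for (x in all_ids) {
    nb <- c(edges$id_b[edges$id_a == x], edges$id_a[edges$id_b == x])
    if (length(nb) < 2L) next
    pr <- utils::combn(sort(nb), 2L)
    for (k in seq_len(ncol(pr))) {
      a <- pr[1L, k]; b <- pr[2L, k]
      d_ab <- obs_num[paste(min(a, b), max(a, b))]
      if (is.na(d_ab)) d_ab <- 7L
      sexes <- ped$ind$sex[match(c(a, b), ped$ind$id)]
      if (d_ab >= 3L && setequal(sexes, c("male", "female"))) {
        forced_parents[[length(forced_parents) + 1L]] <- c(a, x)
        forced_parents[[length(forced_parents) + 1L]] <- c(b, x)
      }
    }
  }
  for (fp in forced_parents) {
    if (can_parent(fp[1L], fp[2L])) {
      ped <- apply_link(fp[1L], fp[2L])
      log <- c(log, sprintf("%s oriented as parent of %s (couple-child triangle)",
                            fp[1L], fp[2L]))
    }
  }
  done_key <- vapply(forced_parents, function(fp) {
    paste(min(fp), max(fp))
  }, character(1))
  todo <- which(!paste(edges$id_a, edges$id_b) %in% done_key)

  repeat {
    progressed <- FALSE
    for (k in todo) {
      a <- edges$id_a[k]; b <- edges$id_b[k]
      fa <- can_parent(a, b); fb <- can_parent(b, a)
      if (fa && fb) next
      if (!fa && !fb) {
        conflicts <- c(conflicts,
                       sprintf("parent-offspring edge %s-%s infeasible in both orientations; suspended",
                               a, b))
        todo <- setdiff(todo, k); progressed <- TRUE; next
      }
      p <- if (fa) a else b; c <- if (fa) b else a
      ped <- apply_link(p, c)
      log <- c(log, sprintf("%s oriented as parent of %s (forced)", p, c))
      todo <- setdiff(todo, k); progressed <- TRUE
    }
    if (!progressed) break
  }
  ## edges feasible in both orientations are deferred to the global
  ## scoring stage; age-at-death ordering (elder as parent when
  ## intervals are disjoint) survives there as the tie-break
  if (length(todo)) deferred <- rbind(deferred, edges[todo, , drop = FALSE])
  list(ped = ped, deferred = deferred, log = log, conflicts = conflicts)
}

## ---------------------------------------------------------------------
## step 2: latent parents

new_latent_id <- function(scaffold) {
  scaffold$latent_counter <- scaffold$latent_counter + 1L
  list(scaffold = scaffold, id = sprintf("LAT%03d", scaffold$latent_counter))
}

#' Infer latent (unsampled) parents
#'
#' Every sibship with fewer than two identified parents gains latent
#' parents, flagged `sampled = FALSE`; a latent mother's mtDNA is set
#' from the children's shared haplogroup.  Children grouped as one
#' sibship but carrying conflicting mtDNA are split into maternal
#' subsets sharing a latent father (the decision is logged).  Children
#' with exactly one identified parent gain the missing latent co-parent
#' so that reproductive unions stay countable.
#'
#' @param scaffold Scaffold from [build_first_degree_scaffold()].
#' @return The scaffold with latent individuals added.
#' @export
infer_latent_parents <- function(scaffold) {
  ped <- scaffold$ped
  log <- scaffold$log

  add_latent <- function(sex, mt = NA_character_) {
    nl <- new_latent_id(scaffold)
    scaffold <<- nl$scaffold
    ped <<- add_individual(ped, nl$id, sex = sex, sampled = FALSE,
                           mt_hap = mt)
    nl$id
  }
  ## guarded setter: refuses links that would close a cycle (possible
  ## when noisy degree records mistype pairs)
  safe_set <- function(child, parent, role) {
    if (child %in% pedigree_ancestors(ped, parent)) {
      log <<- c(log, sprintf(
        "link %s -> %s (%s) skipped: would create a cycle", parent, child,
        role))
      return(invisible(FALSE))
    }
    ped <<- set_parent(ped, child, parent, role)
    invisible(TRUE)
  }

  ## split sibships with conflicting mtDNA into maternal subsets
  sibs <- scaffold$sibships
  out_sibs <- list()
  for (S in sibs) {
    mt <- ped$ind$mt_hap[match(S, ped$ind$id)]
    groups <- split(S, ifelse(is.na(mt), "\r_na", mt))
    known <- setdiff(names(groups), "\r_na")
    if (length(known) > 1L) {
      ## conflicting mtDNA: shared latent father, one latent mother per set
      log <- c(log, sprintf(
        "sibship {%s} split into maternal subsets by mtDNA (%s)",
        paste(S, collapse = ","), paste(known, collapse = " vs ")))
      na_members <- groups[["\r_na"]]
      groups <- groups[known]
      if (length(na_members)) {
        groups[[1L]] <- sort(c(groups[[1L]], na_members))
      }
      fathers <- unique(stats::na.omit(ped$ind$father[match(S, ped$ind$id)]))
      fid <- if (length(fathers) == 1L) fathers[1L] else add_latent("male")
      for (G in groups) {
        mid <- add_latent("female", mt = ped$ind$mt_hap[match(G[1L], ped$ind$id)])
        for (c in G) {
          safe_set(c, fid, "father")
          safe_set(c, mid, "mother")
        }
        out_sibs[[length(out_sibs) + 1L]] <- G
      }
    } else {
      out_sibs[[length(out_sibs) + 1L]] <- S
    }
  }

  ## complete parents of sibships (>= 2 members)
  for (S in out_sibs) {
    i <- match(S, ped$ind$id)
    fa <- unique(stats::na.omit(ped$ind$father[i]))
    mo <- unique(stats::na.omit(ped$ind$mother[i]))
    ## propagate a uniquely identified parent to all members
    if (length(fa) == 1L) for (c in S) safe_set(c, fa, "father")
    if (length(mo) == 1L) for (c in S) safe_set(c, mo, "mother")
    if (length(fa) == 0L) {
      fid <- add_latent("male")
      for (c in S) safe_set(c, fid, "father")
      log <- c(log, sprintf("latent father %s added for sibship {%s}",
                            fid, paste(S, collapse = ",")))
    }
    if (length(mo) == 0L) {
      mt <- unique(stats::na.omit(ped$ind$mt_hap[i]))
      mid <- add_latent("female", mt = if (length(mt) == 1L) mt else NA_character_)
      for (c in S) safe_set(c, mid, "mother")
      log <- c(log, sprintf("latent mother %s added for sibship {%s}",
                            mid, paste(S, collapse = ",")))
    }
  }

  ## latent co-parents for children with exactly one identified parent
  one_par <- which(xor(is.na(ped$ind$father), is.na(ped$ind$mother)))
  for (i in one_par) {
    cid <- ped$ind$id[i]
    if (is.na(ped$ind$father[i])) {
      fid <- add_latent("male")
      safe_set(cid, fid, "father")
    } else {
      mid <- add_latent("female", mt = ped$ind$mt_hap[i])
      safe_set(cid, mid, "mother")
    }
  }

  scaffold$ped <- assign_generations(ped)
  scaffold$sibships <- out_sibs
  scaffold$log <- log
  scaffold
}

## ---------------------------------------------------------------------
## step 3: second-degree classification

#' Load or compute the avuncular / grandparent segment-count calibration
#'
#' Avuncular pairs share their quarter of the genome in more, shorter
#' IBD segments than grandparent-grandchild pairs (three meioses versus
#' two on the connecting path).  The calibration table holds the mean
#' segment count for each class on the default genome map; the midpoint
#' of the two means is the classification threshold.  The packaged table
#' is a versioned fixture produced by [calibrate_segment_counts()].
#'
#' @return Data frame with columns `hypothesis`, `mean_n_segments`,
#'   `sd_n_segments`, `n_rep`, `min_len_cM`, `map_total_cM`.
#' @export
segment_count_calibration <- function() {
  path <- system.file("extdata", "segment_count_calibration.tsv",
                      package = "kinweave")
  if (path == "") stop("calibration fixture not found")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Calibrate the avuncular / grandparent segment-count discriminant
#'
#' Simulates avuncular and grandparent-grandchild pairs by gene dropping
#' on minimal pedigrees and records the mean IBD segment count of each
#' class.
#'
#' @param gm A [genome_model()].
#' @param n_rep Replicates per class.
#' @param min_len_cM Minimum segment length, matching the IBD tables the
#'   discriminant will be applied to.
#' @param seed Seed.
#' @return Calibration data frame (see [segment_count_calibration()]).
#' @export
calibrate_segment_counts <- function(gm = genome_model(), n_rep = 300L,
                                     min_len_cM = 8, seed = 1L) {
  av_ped <- pedigree(data.frame(
    id = c("gf", "gm", "u", "p", "sp", "n"),
    sex = c("male", "female", "male", "female", "male", "male"),
    father = c(NA, NA, "gf", "gf", NA, "sp"),
    mother = c(NA, NA, "gm", "gm", NA, "p"),
    stringsAsFactors = FALSE))
  gp_ped <- pedigree(data.frame(
    id = c("gf", "gm", "p", "sp", "n"),
    sex = c("male", "female", "female", "male", "male"),
    father = c(NA, NA, "gf", NA, "sp"),
    mother = c(NA, NA, "gm", NA, "p"),
    stringsAsFactors = FALSE))
  counts <- function(ped, pair) {
    com <- structure(list(pedigree = ped), class = "simulated_community")
    vapply(seq_len(n_rep), function(r) {
      com <- drop_genomes(com, gm)
      extract_ibd(com, pair[1], pair[2], min_len_cM)$n_segments
    }, numeric(1))
  }
  with_seed(substream_seed(seed, "calibrate"), {
    av <- counts(av_ped, c("u", "n"))
    gp <- counts(gp_ped, c("gf", "n"))
    data.frame(
      hypothesis = c("avuncular", "grandparent_grandchild"),
      mean_n_segments = c(mean(av), mean(gp)),
      sd_n_segments = c(stats::sd(av), stats::sd(gp)),
      n_rep = n_rep, min_len_cM = min_len_cM, map_total_cM = gm$total,
      stringsAsFactors = FALSE)
  })
}

#' Discriminate avuncular from grandparent-grandchild by segment count
#'
#' Classifies by whether the observed IBD segment count exceeds the
#' midpoint of the two calibrated class means (counts only; totals are
#' near-equal for the two classes).
#'
#' @param n_segments Integer vector of observed segment counts.
#' @param calibration Calibration table (default: packaged fixture).
#' @return Character vector, `"avuncular"` or `"grandparent_grandchild"`.
#' @export
discriminate_av_gp <- function(n_segments,
                               calibration = segment_count_calibration()) {
  m_av <- calibration$mean_n_segments[calibration$hypothesis == "avuncular"]
  m_gp <- calibration$mean_n_segments[
    calibration$hypothesis == "grandparent_grandchild"]
  mid <- (m_av + m_gp) / 2
  ifelse(n_segments > mid, "avuncular", "grandparent_grandchild")
}

#' Enumerate and prune second-degree placement hypotheses
#'
#' For each observed second-degree pair not already explained by the
#' scaffold, enumerates the three relationship classes (half-sibling,
#' avuncular, grandparent-grandchild) in all orientations and prunes
#' hypotheses violating the sibling-equality principle (full siblings of
#' one member must be observed at a compatible degree to the other), age
#' feasibility (a parent must have been able to reach the minimum
#' reproductive age; a grandparent needs two generation gaps),
#' haplogroup consistency (paternal-line hypotheses require Y match on
#' male-male chains; maternal-line hypotheses require mtDNA match) and,
#' where both avuncular and grandparent hypotheses survive and an IBD
#' record exists, the segment-count discriminant.
#'
#' @param scaffold Scaffold after [infer_latent_parents()].
#' @param ibd IBD record data frame (may be `NULL`).
#' @param calibration Segment-count calibration table.
#' @return Data frame of candidate placements: pair, `hypothesis`
#'   (`half_sib_father`, `half_sib_mother`, `avuncular`,
#'   `grandparent`), `elder` (the uncle/aunt or grandparent), `younger`,
#'   `side` (`father`/`mother` line of the younger) and `pruned` notes
#'   for dropped hypotheses.
#' @export
classify_second_degree <- function(scaffold, ibd = NULL,
                                   calibration = segment_count_calibration()) {
  ped <- scaffold$ped
  degrees <- scaffold$degrees
  config <- scaffold$config
  d2 <- degrees[degrees$degree == "2", , drop = FALSE]
  if (!nrow(d2)) {
    return(data.frame(id_a = character(), id_b = character(),
                      hypothesis = character(), elder = character(),
                      younger = character(), side = character(),
                      stringsAsFactors = FALSE))
  }
  K <- kinship_matrix(ped)
  exp_deg <- degree_of_kinship(K[cbind(match(d2$id_a, rownames(K)),
                                       match(d2$id_b, rownames(K)))])
  unexplained <- d2[exp_deg != "2", , drop = FALSE]

  ibd_n <- NULL
  if (!is.null(ibd) && nrow(ibd)) {
    ibd_n <- stats::setNames(ibd$n_segments, paste(ibd$id_a, ibd$id_b))
  }
  obs_deg <- stats::setNames(degree_numeric(degrees$degree),
                             paste(degrees$id_a, degrees$id_b))
  obs_of <- function(x, y) {
    v <- obs_deg[paste(min(x, y), max(x, y))]
    if (is.na(v)) 7L else v
  }
  ind <- ped$ind
  row_of <- function(id) ind[match(id, ind$id), ]
  sibs_of <- function(id) {
    for (S in scaffold$sibships) if (id %in% S) return(setdiff(S, id))
    character(0)
  }
  min_age <- config$min_parent_age

  out <- list()
  for (k in seq_len(nrow(unexplained))) {
    a <- unexplained$id_a[k]; b <- unexplained$id_b[k]
    ra <- row_of(a); rb <- row_of(b)
    cands <- list()
    pruned <- character()
    add <- function(hyp, elder, younger, side) {
      cands[[length(cands) + 1L]] <<- data.frame(
        id_a = a, id_b = b, hypothesis = hyp, elder = elder,
        younger = younger, side = side, stringsAsFactors = FALSE)
    }
    prune <- function(msg) pruned <<- c(pruned, msg)

    ## --- half-siblings --------------------------------------------------
    sib_ok <- function(x, y) {
      ## sibling-equality: full sibs of x must be observed near degree 2 to y
      all(vapply(sibs_of(x), function(s) obs_of(s, y) <= 3L, logical(1)))
    }
    hs_father_ok <- !(ra$sex == "male" && rb$sex == "male" &&
                        !is.na(ra$y_hap) && !is.na(rb$y_hap) &&
                        ra$y_hap != rb$y_hap)
    hs_mother_ok <- !(!is.na(ra$mt_hap) && !is.na(rb$mt_hap) &&
                        ra$mt_hap != rb$mt_hap)
    if (hs_father_ok && sib_ok(a, b) && sib_ok(b, a)) {
      add("half_sib_father", a, b, "father")
    } else if (!hs_father_ok) prune("half_sib_father: Y mismatch")
    if (hs_mother_ok && sib_ok(a, b) && sib_ok(b, a)) {
      add("half_sib_mother", a, b, "mother")
    } else if (!hs_mother_ok) prune("half_sib_mother: mtDNA mismatch")

    ## --- avuncular and grandparent, both orientations -------------------
    for (ori in list(c(a, b), c(b, a))) {
      e <- ori[1L]; y <- ori[2L]
      re <- row_of(e); ry <- row_of(y)
      for (side in c("father", "mother")) {
        par_id <- ry[[side]]
        par_known <- !is.na(par_id)
        par_sampled <- par_known && ind$sampled[match(par_id, ind$id)]
        ## avuncular: e is a full sibling of y's `side` parent
        av_ok <- TRUE
        if (par_sampled && !(par_id %in% c(sibs_of(e), e))) {
          av_ok <- FALSE
          prune(sprintf("avuncular(%s via %s): %s's %s is sampled and not %s's sibling",
                        e, side, y, side, e))
        }
        if (av_ok && side == "mother" && !is.na(re$mt_hap) &&
            !is.na(ry$mt_hap) && re$mt_hap != ry$mt_hap) {
          av_ok <- FALSE
          prune(sprintf("avuncular(%s via mother): mtDNA mismatch", e))
        }
        if (av_ok && side == "father" && re$sex == "male" &&
            ry$sex == "male" && !is.na(re$y_hap) && !is.na(ry$y_hap) &&
            re$y_hap != ry$y_hap) {
          av_ok <- FALSE
          prune(sprintf("avuncular(%s via father): Y mismatch", e))
        }
        ## sibling-equality for avuncular: e's sibs are also uncles (deg 2)
        ## unless one of them is y's parent (deg 1)
        if (av_ok &&
            !all(vapply(sibs_of(e), function(s) obs_of(s, y) <= 3L, logical(1)))) {
          av_ok <- FALSE
          prune(sprintf("avuncular(%s via %s): sibling-equality violated", e, side))
        }
        if (av_ok) add("avuncular", e, y, side)

        ## grandparent: e is a parent of y's `side` parent
        gp_ok <- TRUE
        if (!is.na(re$age_high) && re$age_high < 2 * min_age) {
          gp_ok <- FALSE
          prune(sprintf("grandparent(%s): age interval below two generation gaps", e))
        }
        if (gp_ok && re$sex == "unknown") gp_ok <- FALSE
        if (gp_ok && par_sampled) {
          slot <- if (re$sex == "male") "father" else "mother"
          gpar <- ind[[slot]][match(par_id, ind$id)]
          if (!is.na(gpar) && gpar != e) {
            gp_ok <- FALSE
            prune(sprintf("grandparent(%s via %s): slot already filled", e, side))
          }
        }
        if (gp_ok && side == "father" && re$sex == "male" &&
            ry$sex == "male" && !is.na(re$y_hap) && !is.na(ry$y_hap) &&
            re$y_hap != ry$y_hap) {
          gp_ok <- FALSE
          prune(sprintf("grandparent(%s via father): Y mismatch", e))
        }
        if (gp_ok && side == "mother" && re$sex == "female" &&
            !is.na(re$mt_hap) && !is.na(ry$mt_hap) && re$mt_hap != ry$mt_hap) {
          gp_ok <- FALSE
          prune(sprintf("grandparent(%s via mother): mtDNA mismatch", e))
        }
        ## grand-uncle check: e's sibs are degree 3 to y
        if (gp_ok &&
            !all(vapply(sibs_of(e), function(s) obs_of(s, y) <= 4L, logical(1)))) {
          gp_ok <- FALSE
          prune(sprintf("grandparent(%s via %s): sibling degrees inconsistent", e, side))
        }
        if (gp_ok) add("grandparent", e, y, side)
      }
    }

    ## parent-offspring fallback: a true first-degree record can reach
    ## this stage through one step of degree-classification noise, so
    ## both feasible orientations stay in the hypothesis space; the
    ## consistency score arbitrates against the genuine second-degree
    ## hypotheses (which explain the observed degree one step better)
    for (ori in list(c(a, b), c(b, a))) {
      e <- ori[1L]; y <- ori[2L]
      re <- row_of(e); ry <- row_of(y)
      if (!re$sex %in% c("male", "female")) next
      if (!is.na(re$age_high) && re$age_high < min_age) next
      if (re$sex == "female" && !is.na(re$mt_hap) && !is.na(ry$mt_hap) &&
          re$mt_hap != ry$mt_hap) next
      if (re$sex == "male" && ry$sex == "male" && !is.na(re$y_hap) &&
          !is.na(ry$y_hap) && re$y_hap != ry$y_hap) next
      slot <- if (re$sex == "male") "father" else "mother"
      cur <- ry[[slot]]
      if (!is.na(cur) && cur != e && ind$sampled[match(cur, ind$id)]) next
      add("po_parent", e, y, NA_character_)
    }

    cand <- if (length(cands)) do.call(rbind, cands) else NULL
    ## IBD segment-count discriminant between the two surviving classes
    if (!is.null(cand) && !is.null(ibd_n)) {
      n_seg <- ibd_n[paste(a, b)]
      if (!is.na(n_seg) &&
          any(cand$hypothesis == "avuncular") &&
          any(cand$hypothesis == "grandparent")) {
        call_ <- discriminate_av_gp(n_seg, calibration)
        drop_hyp <- if (call_ == "avuncular") "grandparent" else "avuncular"
        pruned <- c(pruned, sprintf(
          "%s pruned by segment-count discriminant (n=%d -> %s)",
          drop_hyp, as.integer(n_seg), call_))
        cand <- cand[cand$hypothesis != drop_hyp, , drop = FALSE]
      }
    }
    if (!is.null(cand) && nrow(cand)) {
      cand$pruned <- paste(pruned, collapse = " | ")
      out[[length(out) + 1L]] <- cand
    } else {
      ## all hypotheses pruned: the pair goes to the alternatives ledger
      out[[length(out) + 1L]] <- data.frame(
        id_a = a, id_b = b, hypothesis = "unplaceable",
        elder = NA_character_, younger = NA_character_,
        side = NA_character_, pruned = paste(pruned, collapse = " | "),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id_a = character(), id_b = character(),
                      hypothesis = character(), elder = character(),
                      younger = character(), side = character(),
                      pruned = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
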