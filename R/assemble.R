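## Step 4: consistency-scored global assembly.
##
## Candidate placements (second-degree hypotheses plus deferred
## first-degree orientations) are inserted greedily in descending order
## of score improvement, with backtracking: a placement whose
## application violates a pedigree invariant (parental sex, <=2 parents,
## mt/Y transmission, acyclicity, minimum reproductive age) is reverted
## and marked infeasible.  Ties are broken by fewer latent individuals,
## then lexicographic order, making assembly deterministic for a fixed
## input order.

## state = list(ped, latent_counter); all helpers return
## list(st = ..., ok = TRUE/FALSE, note = chr, new_latents = int)

st_new_latent <- function(st, sex, mt = NA_character_) {
  st$latent_counter <- st$latent_counter + 1L
  id <- sprintf("LAT%03d", st$latent_counter)
  st$ped <- add_individual(st$ped, id, sex = sex, sampled = FALSE, mt_hap = mt)
  st$new_latents <- (st$new_latents %||% 0L) + 1L
  list(st = st, id = id)
}

st_parent_of <- function(st, id, role) {
  st$ped$ind[[role]][match(id, st$ped$ind$id)]
}

st_is_sampled <- function(st, id) {
  isTRUE(st$ped$ind$sampled[match(id, st$ped$ind$id)])
}

## make a and b share the `role` parent
share_parent <- function(st, a, b, role) {
  pa <- st_parent_of(st, a, role)
  pb <- st_parent_of(st, b, role)
  sexr <- if (role == "father") "male" else "female"
  if (is.na(pa) && is.na(pb)) {
    mt <- NA_character_
    if (role == "mother") {
      mts <- unique(stats::na.omit(
        st$ped$ind$mt_hap[match(c(a, b), st$ped$ind$id)]))
      if (length(mts) == 1L) mt <- mts
    }
    nl <- st_new_latent(st, sexr, mt)
    st <- nl$st
    st$ped <- set_parent(st$ped, a, nl$id, role)
    st$ped <- set_parent(st$ped, b, nl$id, role)
  } else if (is.na(pa)) {
    st$ped <- set_parent(st$ped, a, pb, role)
  } else if (is.na(pb)) {
    st$ped <- set_parent(st$ped, b, pa, role)
  } else if (pa == pb) {
    return(list(st = st, ok = TRUE, note = "already shared"))
  } else if (!st_is_sampled(st, pb)) {
    st$ped <- merge_individuals(st$ped, pb, pa)
  } else if (!st_is_sampled(st, pa)) {
    st$ped <- merge_individuals(st$ped, pa, pb)
  } else {
    return(list(st = st, ok = FALSE,
                note = sprintf("distinct sampled %ss %s and %s", role, pa, pb)))
  }
  list(st = st, ok = TRUE, note = "")
}

## unify the full parent pair of e and p (makes them full siblings)
unify_parents <- function(st, e, p) {
  for (role in c("father", "mother")) {
    res <- share_parent(st, e, p, role)
    if (!res$ok) return(res)
    st <- res$st
  }
  list(st = st, ok = TRUE, note = "")
}

ensure_parent <- function(st, child, role) {
  p <- st_parent_of(st, child, role)
  if (!is.na(p)) return(list(st = st, id = p))
  mt <- NA_character_
  if (role == "mother") mt <- st$ped$ind$mt_hap[match(child, st$ped$ind$id)]
  nl <- st_new_latent(st, if (role == "father") "male" else "female", mt)
  st <- nl$st
  st$ped <- set_parent(st$ped, child, nl$id, role)
  list(st = st, id = nl$id)
}

apply_candidate <- function(st, cand, config) {
  st$new_latents <- 0L
  res <- switch(cand$hypothesis,
    half_sib_father = share_parent(st, cand$id_a, cand$id_b, "father"),
    half_sib_mother = share_parent(st, cand$id_a, cand$id_b, "mother"),
    sibling = unify_parents(st, cand$id_a, cand$id_b),
    avuncular = {
      ep <- ensure_parent(st, cand$younger, cand$side)
      unify_parents(ep$st, cand$elder, ep$id)
    },
    grandparent = {
      ep <- ensure_parent(st, cand$younger, cand$side)
      st2 <- ep$st
      slot <- if (st2$ped$ind$sex[match(cand$elder, st2$ped$ind$id)] == "male")
        "father" else "mother"
      cur <- st_parent_of(st2, ep$id, slot)
      if (is.na(cur)) {
        st2$ped <- set_parent(st2$ped, ep$id, cand$elder, slot)
        list(st = st2, ok = TRUE, note = "")
      } else if (cur == cand$elder) {
        list(st = st2, ok = TRUE, note = "already placed")
      } else if (!st_is_sampled(st2, cur)) {
        st2$ped <- merge_individuals(st2$ped, cur, cand$elder)
        list(st = st2, ok = TRUE, note = "")
      } else {
        list(st = st2, ok = FALSE, note = "grandparent slot filled")
      }
    },
    po_parent = {
      p <- cand$elder; c <- cand$younger
      sexp <- st$ped$ind$sex[match(p, st$ped$ind$id)]
      if (!sexp %in% c("male", "female")) {
        list(st = st, ok = FALSE, note = "parent sex unknown")
      } else {
        role <- if (sexp == "male") "father" else "mother"
        cur <- st_parent_of(st, c, role)
        if (!is.na(cur) && cur != p) {
          if (!st_is_sampled(st, cur)) {
            st$ped <- merge_individuals(st$ped, cur, p)
            list(st = st, ok = TRUE, note = "")
          } else {
            list(st = st, ok = FALSE, note = "parent slot filled")
          }
        } else {
          st$ped <- set_parent(st$ped, c, p, role)
          list(st = st, ok = TRUE, note = "")
        }
      }
    },
    stop("unknown hypothesis: ", cand$hypothesis)
  )
  if (!res$ok) return(res)
  st <- res$st
  viol <- c(validate_pedigree(st$ped), age_gap_violations(st$ped, config))
  if (length(viol)) {
    return(list(st = st, ok = FALSE, note = paste(viol, collapse = "; ")))
  }
  res$st <- st
  res
}

age_gap_violations <- function(ped, config) {
  ind <- ped$ind
  idx <- ped_index(ped)
  viol <- character()
  for (role in c("father", "mother")) {
    p <- idx[ind[[role]]]
    has <- !is.na(p)
    bad <- has & !is.na(ind$age_high[p]) &
      ind$age_high[p] < config$min_parent_age
    if (any(bad, na.rm = TRUE)) {
      viol <- c(viol, paste0(role, " of ", ind$id[which(bad)],
                             " died below reproductive age"))
    }
  }
  viol
}

#' Assemble the pedigree from scaffold and candidate placements
#'
#' Greedy insertion of candidate placements in descending order of
#' consistency-score improvement (see [score_pedigree()]), with
#' backtracking on invariant violations.  Ties are broken by fewer new
#' latent individuals, then lexicographic order.  Alternatives within
#' `alternative_tolerance` of the chosen placement's score are recorded.
#'
#' @param scaffold Scaffold after [infer_latent_parents()].
#' @param candidates Candidate placements from [classify_second_degree()].
#' @param alternative_tolerance Score-delta window within which competing
#'   placements for a pair are kept in the alternatives ledger.
#' @return Object of class `reconstruction_result`: final `pedigree`,
#'   `placements` (applied, in order), `alternatives`, `unplaced_related`
#'   and `unrelated` id vectors, `subpedigrees`, `twin_units`, total
#'   `score` and the decision `log`.
#' @export
assemble_pedigree <- function(scaffold, candidates,
                              alternative_tolerance = 1) {
  config <- scaffold$config
  degrees <- scaffold$degrees
  st <- list(ped = scaffold$ped, latent_counter = scaffold$latent_counter)
  log <- scaffold$log

  ## deferred first-degree edges become orientation candidates
  def <- scaffold$deferred
  def_c <- NULL
  if (!is.null(def) && nrow(def)) {
    ind <- scaffold$ped$ind
    def_c <- do.call(rbind, lapply(seq_len(nrow(def)), function(k) {
      a <- def$id_a[k]; b <- def$id_b[k]
      ra <- ind[match(a, ind$id), ]; rb <- ind[match(b, ind$id), ]
      ## age-ordering preference: elder as parent when intervals disjoint
      prio <- c(0.5, 0.5)
      if (!is.na(ra$age_low) && !is.na(rb$age_low)) {
        if (ra$age_low > rb$age_high) prio <- c(0, 1)
        else if (rb$age_low > ra$age_high) prio <- c(1, 0)
      }
      data.frame(id_a = a, id_b = b,
                 hypothesis = c("po_parent", "po_parent", "sibling"),
                 elder = c(a, b, NA), younger = c(b, a, NA),
                 side = NA_character_, pruned = "", prio = c(prio, 0.5),
                 stringsAsFactors = FALSE)
    }))
  }
  c2 <- candidates[candidates$hypothesis != "unplaceable", , drop = FALSE]
  if (nrow(c2)) c2$prio <- 0.5
  cand <- rbind(c2, def_c)
  unplaceable <- candidates[candidates$hypothesis == "unplaceable", ,
                            drop = FALSE]

  placements <- list()
  alternatives <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand$key <- paste(cand$id_a, cand$id_b)
    ## deterministic base order for tie-breaking
    cand <- cand[order(cand$hypothesis, cand$id_a, cand$id_b,
                       cand$elder, cand$side, method = "radix"), ]
    delta <- rep(NA_real_, nrow(cand))
    latents <- rep(0L, nrow(cand))
    alive <- rep(TRUE, nrow(cand))
    fresh <- rep(FALSE, nrow(cand))
    base_score <- score_pedigree(st$ped, degrees)

    evaluate <- function(k) {
      res <- tryCatch(apply_candidate(st, cand[k, ], config),
                      error = function(e) list(ok = FALSE,
                                               note = conditionMessage(e)))
      if (!res$ok) {
        list(delta = -Inf, latents = 0L)
      } else {
        list(delta = score_pedigree(res$st$ped, degrees) - base_score,
             latents = res$st$new_latents %||% 0L)
      }
    }

    repeat {
      idx_alive <- which(alive)
      if (!length(idx_alive)) break
      repeat {
        ord <- idx_alive[order(-delta[idx_alive], latents[idx_alive],
                               cand$prio[idx_alive], na.last = FALSE)]
        top <- ord[1L]
        if (is.na(delta[top]) || !fresh[top]) {
          ev <- evaluate(top)
          delta[top] <- ev$delta; latents[top] <- ev$latents
          fresh[top] <- TRUE
          next
        }
        break
      }
      if (!is.finite(delta[top]) || delta[top] <= 0) {
        ## before stopping, make sure no stale candidate would still help
        stale <- idx_alive[!fresh[idx_alive]]
        if (length(stale)) {
          for (k in stale) {
            ev <- evaluate(k)
            delta[k] <- ev$delta; latents[k] <- ev$latents; fresh[k] <- TRUE
          }
          next
        }
        break
      }
      ## accept
      res <- apply_candidate(st, cand[top, ], config)
      st <- res$st
      base_score <- base_score + delta[top]
      placements[[length(placements) + 1L]] <- cbind(
        cand[top, c("id_a", "id_b", "hypothesis", "elder", "younger", "side")],
        delta = delta[top], step = length(placements) + 1L)
      log <- c(log, sprintf("placed %s-%s as %s (elder %s via %s), delta %+g",
                            cand$id_a[top], cand$id_b[top],
                            cand$hypothesis[top], cand$elder[top],
                            cand$side[top], delta[top]))
      ## competing placements for the same pair within tolerance go to the
      ## alternatives ledger; all candidates for the pair are retired
      same <- which(alive & cand$key == cand$key[top])
      for (k in setdiff(same, top)) {
        if (fresh[k] && is.finite(delta[k]) &&
            delta[k] >= delta[top] - alternative_tolerance) {
          alternatives[[length(alternatives) + 1L]] <- cbind(
            cand[k, c("id_a", "id_b", "hypothesis", "elder", "younger",
                      "side")],
            delta = delta[k], note = "competing placement within tolerance")
        }
      }
      alive[same] <- FALSE
      fresh[alive] <- FALSE
    }
  }

  for (k in seq_len(nrow(unplaceable))) {
    alternatives[[length(alternatives) + 1L]] <- data.frame(
      id_a = unplaceable$id_a[k], id_b = unplaceable$id_b[k],
      hypothesis = "unplaceable", elder = NA_character_,
      younger = NA_character_, side = NA_character_, delta = NA_real_,
      note = unplaceable$pruned[k], stringsAsFactors = FALSE)
  }

  ped <- assign_generations(st$ped)
  g <- pedigree_graph(ped)
  linked <- igraph::V(g)$name[igraph::degree(g) > 0]
  ids_obs <- unique(c(degrees$id_a, degrees$id_b))
  related_ids <- unique(c(degrees$id_a[degrees$degree != "unrelated"],
                          degrees$id_b[degrees$degree != "unrelated"]))
  sampled_ids <- ped$ind$id[ped$ind$sampled]
  unrelated <- sort(setdiff(sampled_ids, related_ids))
  unplaced <- sort(setdiff(intersect(sampled_ids, related_ids), linked))

  res <- structure(list(
    pedigree = ped,
    placements = if (length(placements)) do.call(rbind, placements) else NULL,
    alternatives = if (length(alternatives)) do.call(rbind, alternatives)
                   else NULL,
    unplaced_related = unplaced,
    unrelated = unrelated,
    twin_units = scaffold$twin_units,
    score = score_pedigree(ped, degrees),
    log = log
  ), class = "reconstruction_result")
  res$subpedigrees <- decompose_subpedigrees(res)
  res
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result> %d individuals (%d latent), score %g\n",
    nrow(x$pedigree$ind), sum(!x$pedigree$ind$sampled), x$score))
  cat(sprintf("  placements: %d; unplaced related: %d; unrelated: %d; subpedigrees: %d\n",
              if (is.null(x$placements)) 0L else nrow(x$placements),
              length(x$unplaced_related), length(x$unrelated),
              length(unique(x$subpedigrees$unit))))
  invisible(x)
}

#' Decompose a pedigree into subpedigree units
#'
#' Connected components of the parent-link graph over linked members
#' (sampled and latent), labelled `S1`, `S2`, ... in decreasing size
#' order with ties broken by the smallest member id.
#'
#' @param x A `reconstruction_result` or a `pedigree`.
#' @return Data frame with columns `id` and `unit`.
#' @export
decompose_subpedigrees <- function(x) {
  ped <- if (inherits(x, "reconstruction_result")) x$pedigree else x
  g <- pedigree_graph(ped)
  keep <- igraph::V(g)$name[igraph::degree(g) > 0]
  if (!length(keep)) {
    return(data.frame(id = character(), unit = character(),
                      stringsAsFactors = FALSE))
  }
  sub <- igraph::induced_subgraph(g, keep)
  memb <- igraph::components(igraph::as_undirected(sub))$membership
  comp <- split(names(memb), memb)
  ord <- order(-vapply(comp, length, integer(1)),
               vapply(comp, function(v) min(v), character(1)))
  comp <- comp[ord]
  do.call(rbind, lapply(seq_along(comp), function(k) {
    data.frame(id = sort(comp[[k]]), unit = sprintf("S%d", k),
               stringsAsFactors = FALSE)
  }))
}

#' Reconstruct a pedigree from observation tables
#'
#' Convenience wrapper chaining [build_first_degree_scaffold()],
#' [infer_latent_parents()], [classify_second_degree()] and
#' [assemble_pedigree()].
#'
#' @param degrees Degree-record data frame.
#' @param metadata Individual metadata.
#' @param ibd Optional IBD record data frame (used by the
#'   avuncular/grandparent discriminant).
#' @param config An [analysis_config()].
#' @param calibration Segment-count calibration table.
#' @return A `reconstruction_result`.
#' @export
reconstruct_pedigree <- function(degrees, metadata, ibd = NULL,
                                 config = analysis_config(),
                                 calibration = segment_count_calibration()) {
  scaffold <- build_first_degree_scaffold(degrees, metadata, config,
                                          ibd = ibd)
  scaffold <- infer_latent_parents(scaffold)
  cands <- classify_second_degree(scaffold, ibd = ibd,
                                  calibration = calibration)
  assemble_pedigree(scaffold, cands)
}

#' Parent-edge recovery against a truth pedigree
#'
#' Compares the parent-child edges among sampled individuals in a
#' reconstructed pedigree with those of the truth pedigree.
#'
#' @param truth,recon Pedigrees.
#' @return List with `recall`, `precision`, `n_true`, `n_recovered`,
#'   `n_spurious`.
#' @export
compare_parent_edges <- function(truth, recon) {
  edge_set <- function(ped) {
    ind <- ped$ind
    sampled <- ind$id[ind$sampled]
    e <- c(paste(ind$id, ind$father, "father")[!is.na(ind$father)],
           paste(ind$id, ind$mother, "mother")[!is.na(ind$mother)])
    keep <- vapply(strsplit(e, " "), function(p) {
      p[1] %in% sampled && p[2] %in% sampled
    }, logical(1))
    e[keep]
  }
  te <- edge_set(truth); re <- edge_set(recon)
  list(recall = if (length(te)) mean(te %in% re) else NA_real_,
       precision = if (length(re)) mean(re %in% te) else NA_real_,
       n_true = length(te), n_recovered = sum(te %in% re),
       n_spurious = sum(!re %in% te))
}
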