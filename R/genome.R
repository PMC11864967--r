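## Gene dropping with crossovers.  A haplotype is a piecewise-constant
## map from genome position (concatenated cM coordinate over all
## autosomes) to a founder-haplotype label, stored as two parallel
## vectors: segment end positions `end` (increasing, final element equals
## the map total) and founder labels `anc`.  Chromosome boundaries are
## always breakpoints, so segments never span chromosomes.

#' Genome model for gene dropping
#'
#' Autosomal genetic map used by the simulator.  Crossovers follow a
#' Haldane (no-interference) process: per meiosis and chromosome the
#' crossover count is Poisson with mean length/100 and positions are
#' uniform.
#'
#' @param lengths_cM Named numeric vector of chromosome map lengths in
#'   centimorgans.  The default is a 22-autosome human-like map scaled to
#'   a 3,400 cM total.
#' @return Object of class `genome_model` with elements `lengths`,
#'   `offsets` (cumulative start of each chromosome) and `total`.
#' @export
genome_model <- function(lengths_cM = NULL) {
  if (is.null(lengths_cM)) {
    raw <- c(286, 269, 223, 214, 204, 192, 187, 168, 166, 181, 158, 175,
             126, 119, 142, 134, 128, 117, 107, 108, 63, 74)
    lengths_cM <- raw * 3400 / sum(raw)
    names(lengths_cM) <- paste0("chr", seq_along(lengths_cM))
  }
  if (any(lengths_cM <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(lengths_cM))) {
    names(lengths_cM) <- paste0("chr", seq_along(lengths_cM))
  }
  gm <- list(lengths = lengths_cM,
             offsets = c(0, cumsum(lengths_cM))[seq_along(lengths_cM)],
             total = sum(lengths_cM))
  names(gm$offsets) <- names(lengths_cM)
  class(gm) <- "genome_model"
  gm
}

## chromosome end positions in the concatenated coordinate
chr_ends <- function(gm) unname(cumsum(gm$lengths))

new_hap <- function(gm, anc) {
  list(end = chr_ends(gm), anc = rep.int(anc, length(gm$lengths)))
}

## value of a piecewise-constant haplotype at interval midpoints
hap_values_at <- function(hap, mids) {
  hap$anc[findInterval(mids, hap$end) + 1L]
}

## collapse consecutive equal-anc segments, never across chromosome ends
merge_hap_runs <- function(end, anc, gm) {
  n <- length(end)
  if (n <= 1L) return(list(end = end, anc = anc))
  ce <- chr_ends(gm)
  keep <- c(anc[-n] != anc[-1L] | (end[-n] %in% ce), TRUE)
  list(end = end[keep], anc = anc[keep])
}

## one meiosis: recombine the two parental haplotypes into a gamete
gamete <- function(h1, h2, gm) {
  nchr <- length(gm$lengths)
  nco <- stats::rpois(nchr, gm$lengths / 100)
  co <- unlist(lapply(seq_len(nchr), function(c) {
    if (nco[c] == 0L) return(numeric(0))
    gm$offsets[c] + sort(stats::runif(nco[c])) * gm$lengths[c]
  }), use.names = FALSE)
  start_hap <- sample(c(1L, 2L), nchr, replace = TRUE)
  ## source haplotype is piecewise constant with breaks at crossovers,
  ## alternating within each chromosome
  ce <- chr_ends(gm)
  src_end <- sort(c(co, ce))
  mids <- (c(0, src_end[-length(src_end)]) + src_end) / 2
  chr_of <- findInterval(mids, ce) + 1L
  ## crossover count before each interval within its chromosome
  co_before <- findInterval(mids, co) -
    c(0, cumsum(tabulate(findInterval(co, ce) + 1L, nchr)))[chr_of]
  src <- ifelse((co_before %% 2L) == 0L, start_hap[chr_of],
                3L - start_hap[chr_of])
  ## stitch: elementary intervals from all breakpoints
  ends <- sort(unique(c(src_end, h1$end, h2$end)))
  emids <- (c(0, ends[-length(ends)]) + ends) / 2
  esrc <- src[findInterval(emids, src_end) + 1L]
  anc <- ifelse(esrc == 1L, hap_values_at(h1, emids), hap_values_at(h2, emids))
  merge_hap_runs(ends, anc, gm)
}

#' Drop genomes through a simulated community
#'
#' Assigns two uniquely labelled founder haplotypes to every pedigree
#' founder and simulates one recombinant gamete per parent-child link
#' (Haldane crossovers), yielding the diploid founder-segment mosaic of
#' every individual.  Haplotype 1 is paternal, haplotype 2 maternal.
#'
#' @param community A `simulated_community` from [simulate_community()].
#' @param gm A [genome_model()].
#' @return The community with `genomes` (named list of per-individual
#'   haplotype pairs) and `genome_model` filled in.
#' @export
drop_genomes <- function(community, gm = genome_model()) {
  ped <- community$pedigree
  ind <- ped$ind
  ord <- topological_order(ped)
  genomes <- vector("list", nrow(ind))
  names(genomes) <- ind$id
  idx <- ped_index(ped)
  next_anc <- 1L
  for (i in ord) {
    fa <- ind$father[i]; mo <- ind$mother[i]
    if (is.na(fa) && is.na(mo)) {
      genomes[[i]] <- list(h1 = new_hap(gm, next_anc),
                           h2 = new_hap(gm, next_anc + 1L))
      next_anc <- next_anc + 2L
    } else if (!is.na(fa) && !is.na(mo)) {
      gf <- genomes[[idx[fa]]]
      gmo <- genomes[[idx[mo]]]
      genomes[[i]] <- list(h1 = gamete(gf$h1, gf$h2, gm),
                           h2 = gamete(gmo$h1, gmo$h2, gm))
    } else {
      stop("individual ", ind$id[i], " has exactly one parent; gene dropping ",
           "requires zero or two")
    }
  }
  community$genomes <- genomes
  community$genome_model <- gm
  community
}

## matched (identical founder label) intervals of two haplotypes, merged
## within chromosomes; returns matrix with columns start, end
matched_intervals <- function(hA, hB, gm) {
  ends <- sort(unique(c(hA$end, hB$end)))
  mids <- (c(0, ends[-length(ends)]) + ends) / 2
  match_ <- hap_values_at(hA, mids) == hap_values_at(hB, mids)
  if (!any(match_)) return(matrix(numeric(0), 0, 2))
  starts <- c(0, ends[-length(ends)])
  ce <- chr_ends(gm)
  ## merge adjacent matched intervals unless separated by a chromosome end
  s <- starts[match_]; e <- ends[match_]
  if (length(s) > 1L) {
    joined <- s[-1L] == e[-length(e)] & !(e[-length(e)] %in% ce)
    grp <- cumsum(c(TRUE, !joined))
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
  }
  cbind(start = as.numeric(s), end = as.numeric(e))
}

segments_to_df <- function(m, gm) {
  if (nrow(m) == 0L) {
    return(data.frame(chr = character(), start_cM = numeric(),
                      end_cM = numeric(), length_cM = numeric(),
                      stringsAsFactors = FALSE))
  }
  chr_i <- findInterval(m[, "start"], chr_ends(gm)) + 1L
  data.frame(chr = names(gm$lengths)[chr_i],
             start_cM = m[, "start"] - gm$offsets[chr_i],
             end_cM = m[, "end"] - gm$offsets[chr_i],
             length_cM = m[, "end"] - m[, "start"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract realised IBD sharing for a pair
#'
#' Intersects the founder-segment mosaics of two individuals over all
#' four haplotype pairings and reports total shared length, segment
#' count, count of segments over 20 cM and the longest segment.  Under
#' this both-haplotype-pair convention a duplicated genome (identical
#' twins) totals twice the map length, the duplicate signature that
#' segment-based detectors report.
#'
#' @param community Community with genomes (see [drop_genomes()]).
#' @param i,j Individual ids.
#' @param min_len_cM Segments shorter than this are dropped (default 8).
#' @return One-row IBD record data frame (see [ibd_record()]) plus a
#'   `segments` attribute with the per-segment table.
#' @export
extract_ibd <- function(community, i, j, min_len_cM = 8) {
  gen <- community$genomes
  if (is.null(gen)) stop("community has no genomes; run drop_genomes() first")
  if (is.null(gen[[i]]) || is.null(gen[[j]])) {
    stop("missing mosaic for ", if (is.null(gen[[i]])) i else j)
  }
  gm <- community$genome_model
  gi <- gen[[i]]; gj <- gen[[j]]
  segs <- rbind(matched_intervals(gi$h1, gj$h1, gm),
                matched_intervals(gi$h1, gj$h2, gm),
                matched_intervals(gi$h2, gj$h1, gm),
                matched_intervals(gi$h2, gj$h2, gm))
  len <- if (nrow(segs)) segs[, "end"] - segs[, "start"] else numeric(0)
  keep <- len >= min_len_cM
  segs <- segs[keep, , drop = FALSE]; len <- len[keep]
  rec <- ibd_record(i, j,
                    total_cM = sum(len),
                    n_segments = length(len),
                    n_segments_gt20 = sum(len > 20),
                    longest_cM = if (length(len)) max(len) else 0)
  attr(rec, "segments") <- segments_to_df(segs, gm)
  rec
}

#' Extract runs of homozygosity
#'
#' Autozygous segments: intervals where both haplotypes of an individual
#' descend from the same founder haplotype.  Their expected total length
#' is the inbreeding coefficient times the map length.
#'
#' @param community Community with genomes.
#' @param i Individual id.
#' @param min_len_cM Minimum reported run length (default 4 cM, the scale
#'   at which haplotype-based ROH callers operate).
#' @return Data frame of segments (`chr`, `start_cM`, `end_cM`,
#'   `length_cM`).
#' @export
extract_roh <- function(community, i, min_len_cM = 4) {
  gen <- community$genomes
  if (is.null(gen)) stop("community has no genomes; run drop_genomes() first")
  if (is.null(gen[[i]])) stop("missing mosaic for ", i)
  gm <- community$genome_model
  m <- matched_intervals(gen[[i]]$h1, gen[[i]]$h2, gm)
  df <- segments_to_df(m, gm)
  df[df$length_cM >= min_len_cM, , drop = FALSE]
}

#' IBD records for a set of pairs
#'
#' Vectorised wrapper around [extract_ibd()].
#'
#' @param community Community with genomes.
#' @param pairs Two-column data frame or matrix of ids (one row per
#'   pair); default all unordered pairs of sampled individuals.
#' @param min_len_cM Minimum segment length retained.
#' @return Data frame of IBD records in canonical order.
#' @export
ibd_table <- function(community, pairs = NULL, min_len_cM = 8) {
  ind <- community$pedigree$ind
  if (is.null(pairs)) {
    ids <- sort(ind$id[ind$sampled])
    if (length(ids) < 2L) return(empty_ibd_records())
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  recs <- lapply(seq_len(nrow(pairs)), function(k) {
    r <- extract_ibd(community, pairs[k, 1L], pairs[k, 2L], min_len_cM)
    attr(r, "segments") <- NULL
    r
  })
  canonical_pairs(do.call(rbind, recs))
}
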