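## Pairwise observation tables: relatedness degrees (KIN-style) and IBD
## segment summaries (ancIBD-style).  Pairs are unordered; canonical
## lexicographic order (id_a < id_b) is enforced at a single point.

DEGREE_LEVELS <- c("identical", as.character(1:6), "unrelated")

empty_degree_records <- function() {
  data.frame(id_a = character(), id_b = character(), degree = character(),
             first_degree_type = character(), source = character(),
             stringsAsFactors = FALSE)
}

empty_ibd_records <- function() {
  data.frame(id_a = character(), id_b = character(), total_cM = numeric(),
             n_segments = integer(), n_segments_gt20 = integer(),
             longest_cM = numeric(), stringsAsFactors = FALSE)
}

#' Canonicalise pair ordering
#'
#' Swaps `id_a`/`id_b` so that `id_a < id_b` lexicographically; the one
#' normalisation point for all pairwise tables.  Idempotent.
#'
#' @param df Data frame with `id_a`, `id_b` columns.
#' @return The data frame with pairs in canonical order.
#' @export
canonical_pairs <- function(df) {
  a <- as.character(df$id_a); b <- as.character(df$id_b)
  swap <- a > b
  df$id_a <- ifelse(swap, b, a)
  df$id_b <- ifelse(swap, a, b)
  df
}

check_duplicate_pairs <- function(df, what) {
  key <- paste(df$id_a, df$id_b, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate pair(s) in ", what, ": ",
         paste(gsub("\r", "-", dup), collapse = ", "))
  }
  invisible(df)
}

#' Build a degree-record table
#'
#' One row per unordered pair with its estimated relatedness degree
#' (`"identical"`, `"1"` ... `"6"` or `"unrelated"`) and, for degree-1
#' pairs, the first-degree type.
#'
#' @param id_a,id_b Pair ids (order-free; canonicalised).
#' @param degree Degree labels.
#' @param first_degree_type `"parent_offspring"`, `"sibling"` or
#'   `"unknown"` (forced to `"unknown"` for non-first-degree rows).
#' @param source Free-text provenance tag.
#' @return Data frame of degree records in canonical order.
#' @export
degree_record <- function(id_a, id_b, degree,
                          first_degree_type = "unknown", source = "obs") {
  bad <- !(degree %in% DEGREE_LEVELS)
  if (any(bad)) stop("invalid degree label(s): ",
                     paste(unique(degree[bad]), collapse = ", "))
  df <- data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                   degree = as.character(degree),
                   first_degree_type = as.character(first_degree_type),
                   source = as.character(source), stringsAsFactors = FALSE)
  df$first_degree_type[df$degree != "1"] <- "unknown"
  df <- canonical_pairs(df)
  check_duplicate_pairs(df, "degree table")
  df
}

#' Build an IBD-record table
#'
#' One row per unordered pair with genome-wide IBD sharing summaries:
#' total length, segment count, count of long (>20 cM) segments and the
#' longest segment.
#'
#' @param id_a,id_b Pair ids (canonicalised).
#' @param total_cM Total shared length in centimorgans.
#' @param n_segments Number of shared segments.
#' @param n_segments_gt20 Number of segments longer than 20 cM.
#' @param longest_cM Longest shared segment.
#' @return Data frame of IBD records in canonical order.
#' @export
ibd_record <- function(id_a, id_b, total_cM, n_segments,
                       n_segments_gt20, longest_cM) {
  df <- data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                   total_cM = as.numeric(total_cM),
                   n_segments = as.integer(n_segments),
                   n_segments_gt20 = as.integer(n_segments_gt20),
                   longest_cM = as.numeric(longest_cM),
                   stringsAsFactors = FALSE)
  if (any(df$n_segments_gt20 > df$n_segments)) {
    stop("n_segments_gt20 exceeds n_segments")
  }
  if (any(df$longest_cM > df$total_cM + 1e-9)) {
    stop("longest_cM exceeds total_cM")
  }
  df <- canonical_pairs(df)
  check_duplicate_pairs(df, "IBD table")
  df
}

read_pair_table <- function(path, required, what) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse ", what, " table '", path, "': ",
                             conditionMessage(e))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(is.na(df$id_a) | is.na(df$id_b) | df$id_a == "" | df$id_b == "")
  if (length(bad)) {
    stop("malformed row ", bad[1] + 1L, " in ", what, " table '", path,
         "': missing pair id")
  }
  df
}

#' Read a degree table
#'
#' Tab-separated, UTF-8, header row with at least `id_a`, `id_b`,
#' `degree`; optional `first_degree_type` and `source`.  Unknown columns
#' are preserved on read but ignored downstream.  Pairs are
#' canonicalised; duplicate pairs are an integrity error.
#'
#' @param path File path.
#' @return Data frame of degree records.
#' @export
read_degree_table <- function(path) {
  df <- read_pair_table(path, c("id_a", "id_b", "degree"), "degree")
  if (!"first_degree_type" %in% names(df)) {
    df$first_degree_type <- rep("unknown", nrow(df))
  }
  if (!"source" %in% names(df)) df$source <- rep(basename(path), nrow(df))
  bad <- which(!(df$degree %in% DEGREE_LEVELS))
  if (length(bad)) {
    stop("malformed row ", bad[1] + 1L, " in degree table '", path,
         "': invalid degree '", df$degree[bad[1]], "'")
  }
  df <- canonical_pairs(df)
  check_duplicate_pairs(df, "degree table")
  df$first_degree_type[is.na(df$first_degree_type) | df$degree != "1"] <- "unknown"
  df
}

#' Read an IBD table
#'
#' Tab-separated with columns `id_a`, `id_b`, `total_cM`, `n_segments`,
#' `n_segments_gt20`, `longest_cM`.
#'
#' @param path File path.
#' @return Data frame of IBD records.
#' @export
read_ibd_table <- function(path) {
  df <- read_pair_table(path, c("id_a", "id_b", "total_cM", "n_segments",
                                "n_segments_gt20", "longest_cM"), "IBD")
  num <- c("total_cM", "n_segments", "n_segments_gt20", "longest_cM")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad)) {
      stop("malformed row ", bad[1] + 1L, " in IBD table '", path,
           "': non-numeric ", cn)
    }
    df[[cn]] <- v
  }
  df <- canonical_pairs(df)
  check_duplicate_pairs(df, "IBD table")
  df
}

#' Read an individual-metadata table
#'
#' Tab-separated with at least an `id` column; any subset of the
#' individual fields described in [pedigree()] is recognised.
#'
#' @param path File path.
#' @return Data frame with the full canonical column set.
#' @export
read_metadata <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse metadata table '", path, "': ",
                             conditionMessage(e))
  )
  if (!"id" %in% names(df)) stop("metadata table '", path, "' lacks 'id'")
  if (anyDuplicated(df$id)) {
    stop("duplicate individual id(s) in metadata table '", path, "'")
  }
  complete_individuals(df)
}

#' Write a tab-separated table
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' IBD-based relatedness classifier
#'
#' A pair is called related within first-to-sixth degree when it shares
#' strictly more than `min_long_segments` segments each longer than
#' `long_segment_cM` (defaults: more than two segments over 20 cM).
#'
#' @param records IBD record data frame.
#' @param config An [analysis_config()] list.
#' @return Logical vector, one per record.
#' @export
classify_ibd_relatedness <- function(records, config = analysis_config()) {
  records$n_segments_gt20 > config$min_long_segments
}

#' Analysis configuration
#'
#' Thresholds and knobs shared across the pipeline, mirroring the YAML
#' configuration schema field-for-field.
#'
#' @param long_segment_cM Length above which a segment counts as "long"
#'   for the relatedness classifier (default 20).
#' @param min_long_segments A pair is related when its count of long
#'   segments strictly exceeds this (default 2).
#' @param network_segment_cM Segment-length threshold for the
#'   `sum_threshold` network tie rule (default 16).
#' @param roh_min_cM Minimum run-of-homozygosity length (default 4).
#' @param ibd_min_cM Minimum segment length retained when extracting IBD
#'   from simulated genomes (default 8, the scale at which segment-based
#'   detectors operate reliably).
#' @param min_parent_age Minimum age (years) at which an individual can
#'   have reproduced; one generation gap (default 15).
#' @param ergm_terms Default dyadic covariate terms.
#' @param n_permutations Permutation count for QAP tests.
#' @param status_item_set Flags that count as prestige objects.
#' @param twin_total_cM IBD total above which a pair carries the
#'   duplicate (twin) signature; about 1.5 times the map length.
#' @param seed Base seed for stochastic stages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(long_segment_cM = 20, min_long_segments = 2L,
                            network_segment_cM = 16, roh_min_cM = 4,
                            ibd_min_cM = 8, min_parent_age = 15,
                            ergm_terms = c("sex_pairing", "status_count"),
                            n_permutations = 999L,
                            status_item_set = c("belt_set", "coat_clasp"),
                            twin_total_cM = 5000, seed = 1L) {
  cfg <- list(long_segment_cM = long_segment_cM,
              min_long_segments = min_long_segments,
              network_segment_cM = network_segment_cM,
              roh_min_cM = roh_min_cM, ibd_min_cM = ibd_min_cM,
              min_parent_age = min_parent_age, ergm_terms = ergm_terms,
              n_permutations = as.integer(n_permutations),
              status_item_set = status_item_set,
              twin_total_cM = twin_total_cM, seed = as.integer(seed))
  thr <- c(cfg$long_segment_cM, cfg$network_segment_cM, cfg$roh_min_cM,
           cfg$ibd_min_cM, cfg$min_parent_age)
  if (any(thr <= 0)) stop("analysis thresholds must be positive")
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror [analysis_config()] arguments.
#' @return An `analysis_config` list.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown analysis_config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(analysis_config, vals)
}
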