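## Reproductive-practice statistics computed on an assembled pedigree:
## demographic profiles, reproductive unions and levirate detection,
## lineage classification, exogamy and juvenile sex ratios, and
## consanguinity checks.

#' Per-generation demographic profile
#'
#' Contingency table of generation by age category by sex over sampled
#' pedigree members.  Individuals with an unknown age category are
#' counted in an explicit `unknown` column, never dropped.
#'
#' @param ped A `pedigree` with generations assigned.
#' @return A 3-way `table` (generation x age category x sex) whose grand
#'   total equals the number of sampled members.
#' @export
demographic_profile <- function(ped) {
  ind <- ped$ind[ped$ind$sampled, , drop = FALSE]
  acat <- factor(ifelse(is.na(ind$age_category), "unknown", ind$age_category),
                 levels = c(AGE_CATEGORIES, "unknown"))
  sex <- factor(ind$sex, levels = c("male", "female", "unknown"))
  gen <- factor(ind$generation, levels = sort(unique(ind$generation)))
  table(generation = gen, age_category = acat, sex = sex)
}

#' Enumerate reproductive unions
#'
#' A reproductive relation is a distinct parent pair with at least one
#' child; latent parents count.  A union is multi-reproductive when
#' either parent appears in two or more unions.  The single-to-multiple
#' ratio is reported as `round((n_relations - n_multi) / n_multi) : 1`
#' alongside the raw fraction.  Children with only one known parent are
#' listed separately as half-unions and excluded from the ratio.
#'
#' @param ped A `pedigree`.
#' @return List with `unions` (data frame: `father`, `mother`,
#'   `n_children`, `children`, `father_multi`, `mother_multi`, `multi`),
#'   `half_unions`, and `summary` (`n_relations`, `n_multi`,
#'   `single_multi_ratio`, `ratio_label`).
#' @export
enumerate_unions <- function(ped) {
  ind <- ped$ind
  both <- !is.na(ind$father) & !is.na(ind$mother)
  key <- paste(ind$father[both], ind$mother[both], sep = "\r")
  fams <- split(ind$id[both], key)
  unions <- data.frame(
    father = sub("\r.*", "", names(fams)),
    mother = sub(".*\r", "", names(fams)),
    n_children = vapply(fams, length, integer(1)),
    children = vapply(fams, function(x) paste(sort(x), collapse = ","),
                      character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  unions <- unions[order(unions$father, unions$mother), , drop = FALSE]
  unions$father_multi <- unions$father %in%
    unions$father[duplicated(unions$father)]
  unions$mother_multi <- unions$mother %in%
    unions$mother[duplicated(unions$mother)]
  unions$multi <- unions$father_multi | unions$mother_multi

  one <- xor(is.na(ind$father), is.na(ind$mother))
  half <- data.frame(
    parent = ifelse(is.na(ind$father[one]), ind$mother[one], ind$father[one]),
    child = ind$id[one], stringsAsFactors = FALSE)

  n_rel <- nrow(unions)
  n_multi <- sum(unions$multi)
  ratio <- if (n_multi == 0L) Inf else (n_rel - n_multi) / n_multi
  label <- if (n_multi == 0L) "all single" else
    sprintf("%d:1", round(ratio))
  list(unions = unions, half_unions = half,
       summary = list(n_relations = n_rel, n_multi = n_multi,
                      single_multi_ratio = ratio, ratio_label = label))
}

#' Single-to-multiple union ratio from counts
#'
#' @param n_relations Total reproductive relations.
#' @param n_multi Multi-reproductive unions among them.
#' @return List with the raw ratio and the rounded `ratio_label`
#'   (`"3:1"` style); `"all single"` when `n_multi` is zero.
#' @export
union_ratio <- function(n_relations, n_multi) {
  ratio <- if (n_multi == 0) Inf else (n_relations - n_multi) / n_multi
  list(ratio = ratio,
       rounded = if (is.finite(ratio)) round(ratio) else Inf,
       ratio_label = if (n_multi == 0) "all single" else
         sprintf("%d:1", round(ratio)))
}

#' Detect levirate unions
#'
#' For each mother with two or more reproductive partners, the unions
#' are flagged as levirate when any two of her partners are male
#' relatives of each other at second degree or closer, or stand in a
#' stepson relation (one partner is a son of another partner by a
#' different woman).  Cross-generation arrangements (for example a
#' grandson of the deceased) qualify through the degree rule.
#'
#' @param ped A `pedigree`.
#' @param unions Output of [enumerate_unions()] (recomputed if omitted).
#' @return List with `mothers` (data frame: `mother`, `partners`,
#'   `levirate`, `evidence`) and `n_levirate`, plus the unions table with
#'   a `levirate` flag.
#' @export
detect_levirate <- function(ped, unions = enumerate_unions(ped)) {
  u <- unions$unions
  K <- kinship_matrix(ped)
  ind <- ped$ind
  mothers <- unique(u$mother[u$mother_multi])
  res <- lapply(mothers, function(m) {
    partners <- sort(unique(u$father[u$mother == m]))
    lev <- FALSE; ev <- character()
    pr <- utils::combn(partners, 2L)
    for (k in seq_len(ncol(pr))) {
      p1 <- pr[1L, k]; p2 <- pr[2L, k]
      phi <- K[p1, p2]
      if (degree_numeric(degree_of_kinship(phi)) <= 2L) {
        lev <- TRUE
        ev <- c(ev, sprintf("%s and %s related (phi=%.4g)", p1, p2, phi))
      } else {
        ## stepson: one partner is the other's son by a different woman
        r1 <- ind[match(p1, ind$id), ]; r2 <- ind[match(p2, ind$id), ]
        step <- (identical(r1$father, p2) && !identical(r1$mother, m)) ||
          (identical(r2$father, p1) && !identical(r2$mother, m))
        if (step) {
          lev <- TRUE
          ev <- c(ev, sprintf("%s is a stepson-line partner of %s", p1, p2))
        }
      }
    }
    data.frame(mother = m, partners = paste(partners, collapse = ","),
               levirate = lev, evidence = paste(ev, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  mothers_df <- if (length(res)) do.call(rbind, res) else
    data.frame(mother = character(), partners = character(),
               levirate = logical(), evidence = character(),
               stringsAsFactors = FALSE)
  u$levirate <- u$mother %in% mothers_df$mother[mothers_df$levirate]
  list(mothers = mothers_df, n_levirate = sum(mothers_df$levirate),
       unions = u)
}

#' Classify descent lines as patrilineages, matrilineages or bilineages
#'
#' Descent lines are maximal parent-to-child transmission chains among
#' reproducing pedigree members (each member of a chain has children; a
#' chain spans as many generations as it has members).  Within each
#' maximal root-to-leaf descent path, maximal runs of same-sex
#' transmission of at least `min_span` members are recorded as
#' patrilineages (father-to-child throughout) or matrilineages
#' (mother-to-child throughout); a path spanning `min_span` generations
#' or more that contains no such consistent run — transmission switched
#' sex before reaching `min_span` generations — is recorded as a
#' bilineage.  Lines wholly contained in a longer recorded line of the
#' same class are not double counted.  Proportions are over classified
#' lines; a pedigree shallower than `min_span` generations yields an
#' explicit `NULL` proportion set, not zeros.
#'
#' @param ped A `pedigree`.
#' @param min_span Minimum line span in generations (default 3; shorter
#'   stretches of consistent transmission are not called).
#' @return List with `lines` (data frame: `line_id`, `class`, `span`,
#'   `members`) and `proportions` (named vector or `NULL`).
#' @export
classify_lineages <- function(ped, min_span = 3L) {
  ind <- ped$ind
  idx <- ped_index(ped)
  reproduces <- ind$id %in% c(ind$father, ind$mother)
  children <- vector("list", nrow(ind))
  role <- vector("list", nrow(ind))
  for (i in seq_len(nrow(ind))) {
    for (r in c("father", "mother")) {
      p <- ind[[r]][i]
      if (!is.na(p) && reproduces[i]) {
        ## transmission graph: both ends reproduce
        j <- idx[p]
        children[[j]] <- c(children[[j]], i)
        role[[j]] <- c(role[[j]], r)
      }
    }
  }
  rep_of <- function(id) {
    j <- match(id, ind$id)
    !is.na(j) & reproduces[j]
  }
  has_rep_parent <- rep_of(ind$father) | rep_of(ind$mother)
  has_rep_parent[is.na(has_rep_parent)] <- FALSE
  roots <- which(reproduces & !has_rep_parent)
  paths <- list()
  walk <- function(i, acc, roles) {
    ch <- children[[i]]
    if (!length(ch)) {
      paths[[length(paths) + 1L]] <<- list(members = c(acc, i), roles = roles)
      return(invisible())
    }
    for (k in seq_along(ch)) {
      walk(ch[k], c(acc, i), c(roles, role[[i]][k]))
    }
  }
  for (r in roots) walk(r, integer(0), character(0))

  patri <- list(); matri <- list(); bi <- list()
  for (p in paths) {
    n <- length(p$members)
    if (n < min_span) next
    ## maximal same-type runs of transmission links
    runs <- rle(p$roles)
    pos <- cumsum(c(1L, runs$lengths))
    consistent <- FALSE
    for (k in seq_along(runs$lengths)) {
      if (runs$lengths[k] + 1L >= min_span) {
        consistent <- TRUE
        members <- p$members[pos[k]:(pos[k] + runs$lengths[k])]
        if (runs$values[k] == "father") {
          patri[[length(patri) + 1L]] <- members
        } else {
          matri[[length(matri) + 1L]] <- members
        }
      }
    }
    if (!consistent) {
      ## bilineage requires a genuine descent switch: a leading single
      ## mother link is just the co-parent of a paternal line (every
      ## line starts at somebody's mother), so the switch after it does
      ## not count; any other change of transmitting sex does
      nl <- length(p$roles)
      genuine <- any(vapply(seq_len(nl - 1L), function(k) {
        p$roles[k] != p$roles[k + 1L] &&
          !(k == 1L && p$roles[1L] == "mother")
      }, logical(1)))
      if (genuine) bi[[length(bi) + 1L]] <- p$members
    }
  }

  dedupe <- function(lst) {
    if (!length(lst)) return(lst)
    keys <- vapply(lst, function(m) paste0(",", paste(m, collapse = ","), ","),
                   character(1))
    keep <- !duplicated(keys)
    lst <- lst[keep]; keys <- keys[keep]
    ## drop lines wholly contained in a longer line of the same class
    contained <- vapply(seq_along(keys), function(i) {
      any(vapply(seq_along(keys), function(j) {
        i != j && nchar(keys[j]) > nchar(keys[i]) &&
          grepl(keys[i], keys[j], fixed = TRUE)
      }, logical(1)))
    }, logical(1))
    lst[!contained]
  }
  patri <- dedupe(patri); matri <- dedupe(matri); bi <- dedupe(bi)

  mk <- function(lst, cls) {
    if (!length(lst)) return(NULL)
    data.frame(class = cls, span = vapply(lst, length, integer(1)),
               members = vapply(lst, function(m) {
                 paste(ind$id[m], collapse = ",")
               }, character(1)), stringsAsFactors = FALSE)
  }
  lines <- rbind(mk(patri, "patrilineage"), mk(matri, "matrilineage"),
                 mk(bi, "bilineage"))
  if (is.null(lines) || !nrow(lines)) {
    return(list(lines = data.frame(line_id = character(), class = character(),
                                   span = integer(), members = character(),
                                   stringsAsFactors = FALSE),
                proportions = NULL))
  }
  lines <- lines[order(-lines$span, lines$members), , drop = FALSE]
  lines <- cbind(line_id = sprintf("L%03d", seq_len(nrow(lines))), lines,
                 stringsAsFactors = FALSE)
  rownames(lines) <- NULL
  prop <- prop.table(table(factor(lines$class,
                                  levels = c("patrilineage", "matrilineage",
                                             "bilineage"))))
  list(lines = lines, proportions = c(prop))
}

#' Mother exogamy statistics
#'
#' Mothers are sampled females with at least one sampled child; a mother
#' is exogamous ("without ancestors") when neither a parent nor a
#' grandparent of hers is sampled on site.  Because excavated counts may
#' or may not include mothers known only as latent nodes, both variants
#' are reported.
#'
#' @param ped A `pedigree`.
#' @param site Optional site code; restricts to individuals of that site.
#' @return List with `mothers_total`, `mothers_without_ancestors`,
#'   `fraction`, and `latent_variant` (same fields with latent mothers of
#'   sampled children included in the denominator).
#' @export
exogamy_stats <- function(ped, site = NULL) {
  ind <- ped$ind
  on_site <- ind$sampled & (if (is.null(site)) TRUE else ind$site %in% site)
  sampled_ids <- ind$id[on_site]
  kids_of <- function(id) {
    ind$id[(ind$father %in% id | ind$mother %in% id) & ind$sampled]
  }
  has_site_ancestor <- function(id) {
    r <- ind[match(id, ind$id), ]
    pars <- stats::na.omit(c(r$father, r$mother))
    if (any(pars %in% sampled_ids)) return(TRUE)
    gps <- unlist(lapply(pars, function(p) {
      rp <- ind[match(p, ind$id), ]
      c(rp$father, rp$mother)
    }))
    any(stats::na.omit(gps) %in% sampled_ids)
  }
  mothers <- ind$id[on_site & ind$sex == "female"]
  mothers <- mothers[vapply(mothers, function(m) length(kids_of(m)) > 0,
                            logical(1))]
  noanc <- vapply(mothers, function(m) !has_site_ancestor(m), logical(1))

  lat_mothers <- ind$id[!ind$sampled & ind$sex == "female"]
  lat_mothers <- lat_mothers[vapply(lat_mothers,
                                    function(m) length(kids_of(m)) > 0,
                                    logical(1))]
  lat_noanc <- vapply(lat_mothers, function(m) !has_site_ancestor(m),
                      logical(1))

  list(
    mothers_total = length(mothers),
    mothers_without_ancestors = sum(noanc),
    fraction = if (length(mothers)) mean(noanc) else NA_real_,
    latent_variant = list(
      mothers_total = length(mothers) + length(lat_mothers),
      mothers_without_ancestors = sum(noanc) + sum(lat_noanc),
      fraction = if (length(mothers) + length(lat_mothers) > 0)
        (sum(noanc) + sum(lat_noanc)) /
          (length(mothers) + length(lat_mothers)) else NA_real_
    )
  )
}

#' Juvenile sex ratio of the deceased
#'
#' Ratio of deceased males to females whose age-at-death interval
#' midpoint lies in `[age_low, age_high]` years.  Individuals of unknown
#' sex are excluded but counted.
#'
#' @param metadata Individual metadata (or a pedigree's individuals
#'   table).
#' @param age_low,age_high Age window in years (default 7-17).
#' @return List with `n_male`, `n_female`, `n_unknown_sex`, `ratio`
#'   (males per female; `Inf` with `infinite = TRUE` marker when no
#'   females fall in the window) and `ratio_label`.
#' @export
juvenile_sex_ratio <- function(metadata, age_low = 7, age_high = 17) {
  ind <- if (inherits(metadata, "pedigree")) metadata$ind else
    complete_individuals(metadata)
  mid <- (ind$age_low + ind$age_high) / 2
  inw <- !is.na(mid) & mid >= age_low & mid <= age_high
  nm <- sum(inw & ind$sex == "male")
  nf <- sum(inw & ind$sex == "female")
  nu <- sum(inw & !(ind$sex %in% c("male", "female")))
  ratio <- if (nf == 0L) Inf else nm / nf
  list(n_male = nm, n_female = nf, n_unknown_sex = nu, ratio = ratio,
       infinite = nf == 0L,
       ratio_label = if (nf == 0L) "no females in range" else
         sprintf("%.1f:1", ratio))
}

#' Consanguinity check
#'
#' Computes the pedigree inbreeding coefficient of every member and
#' flags positive values; when a runs-of-homozygosity table is supplied
#' the genomic route is applied as well (total ROH above
#' `roh_flag_fraction` of the map length).  The site verdict is
#' "consanguinity absent" only when no individual is flagged.
#'
#' @param ped A `pedigree`.
#' @param roh_table Optional data frame with columns `id` and
#'   `total_roh_cM`.
#' @param map_length_cM Genome map length used to scale the ROH flag.
#' @param roh_flag_fraction Fraction of the map above which total ROH is
#'   flagged (default `1/32`, half the first-cousin expectation).
#' @return List with `individuals` (data frame: `id`, `F`, `flag_pedigree`,
#'   `total_roh_cM`, `flag_roh`), and `verdict` (`"consanguinity absent"`
#'   or `"consanguinity present"`).
#' @export
consanguinity_check <- function(ped, roh_table = NULL,
                                map_length_cM = genome_model()$total,
                                roh_flag_fraction = 1 / 32) {
  ind <- ped$ind
  K <- kinship_matrix(ped)
  Fi <- vapply(seq_len(nrow(ind)), function(i) {
    fa <- ind$father[i]; mo <- ind$mother[i]
    if (is.na(fa) || is.na(mo)) 0 else K[fa, mo]
  }, numeric(1))
  df <- data.frame(id = ind$id, F = Fi, flag_pedigree = Fi > 0,
                   total_roh_cM = NA_real_, flag_roh = NA,
                   stringsAsFactors = FALSE)
  if (!is.null(roh_table)) {
    m <- match(df$id, roh_table$id)
    df$total_roh_cM <- roh_table$total_roh_cM[m]
    df$flag_roh <- !is.na(df$total_roh_cM) &
      df$total_roh_cM > roh_flag_fraction * map_length_cM
  }
  flagged <- df$flag_pedigree | (!is.na(df$flag_roh) & df$flag_roh)
  list(individuals = df,
       verdict = if (any(flagged)) "consanguinity present"
                 else "consanguinity absent")
}
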