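## Pedigree serialisation: PLINK-style FAM records and GraphML with full
## node attributes.

#' Convert a pedigree to an igraph graph
#'
#' Directed graph with one parent-to-child edge per known link, edge
#' attribute `role` in `{"father", "mother"}`, and all individual fields
#' as vertex attributes.
#'
#' @param ped A `pedigree`.
#' @return An `igraph` object.
#' @export
pedigree_graph <- function(ped) {
  ind <- ped$ind
  edges <- rbind(
    data.frame(from = ind$father, to = ind$id, role = "father",
               stringsAsFactors = FALSE),
    data.frame(from = ind$mother, to = ind$id, role = "mother",
               stringsAsFactors = FALSE)
  )
  edges <- edges[!is.na(edges$from), , drop = FALSE]
  vattr <- ind
  names(vattr)[names(vattr) == "id"] <- "name"
  ## igraph attribute writers dislike NA logicals in graphml; keep plain
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vattr)
  g
}

#' Write a pedigree as FAM + GraphML
#'
#' The FAM file holds PLINK-style records (`family`, `id`, `father`,
#' `mother`, `sex`, `phenotype` placeholder `-9`), with `0` for missing
#' parents and family ids taken from connected components.  The GraphML
#' file carries every individual field as a node attribute.
#'
#' @param ped A `pedigree`.
#' @param fam_path,graphml_path Output paths (either may be `NULL` to
#'   skip that format).
#' @return Invisibly, the list of paths written.
#' @export
write_pedigree <- function(ped, fam_path = NULL, graphml_path = NULL) {
  written <- list()
  if (!is.null(fam_path)) {
    ind <- ped$ind
    g <- pedigree_graph(ped)
    comp <- igraph::components(igraph::as_undirected(g))$membership
    fam <- data.frame(
      family = paste0("F", comp[ind$id]),
      id = ind$id,
      father = ifelse(is.na(ind$father), "0", ind$father),
      mother = ifelse(is.na(ind$mother), "0", ind$mother),
      sex = c(male = 1L, female = 2L, unknown = 0L)[ind$sex],
      phenotype = -9L,
      stringsAsFactors = FALSE
    )
    utils::write.table(fam, fam_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written$fam <- fam_path
  }
  if (!is.null(graphml_path)) {
    g <- pedigree_graph(ped)
    ## graphml cannot hold NA; encode as empty string / sentinel
    for (at in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, at)
      if (is.character(v)) v[is.na(v)] <- ""
      if (is.logical(v)) v <- as.integer(v)
      if (is.numeric(v)) v[is.na(v)] <- NaN
      g <- igraph::set_vertex_attr(g, at, value = v)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
    written$graphml <- graphml_path
  }
  invisible(written)
}

#' Read a pedigree from a FAM file
#'
#' @param path FAM file written by [write_pedigree()] (or PLINK).
#' @return A `pedigree`; individuals referenced only as parents are added
#'   with unknown metadata.
#' @export
read_pedigree_fam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father",
                                         "mother", "sex", "phenotype"))
  fam$father[fam$father == "0"] <- NA_character_
  fam$mother[fam$mother == "0"] <- NA_character_
  sex <- c("unknown", "male", "female")[fam$sex + 1L]
  extra_f <- setdiff(stats::na.omit(fam$father), fam$id)
  extra_m <- setdiff(stats::na.omit(fam$mother), fam$id)
  ind <- data.frame(id = c(fam$id, extra_f, extra_m),
                    father = c(fam$father, rep(NA, length(extra_f) + length(extra_m))),
                    mother = c(fam$mother, rep(NA, length(extra_f) + length(extra_m))),
                    sex = c(sex, rep("male", length(extra_f)),
                            rep("female", length(extra_m))),
                    stringsAsFactors = FALSE)
  pedigree(ind)
}

#' Read a pedigree from GraphML
#'
#' @param path GraphML file written by [write_pedigree()].
#' @return A `pedigree` with all node attributes restored.
#' @export
read_pedigree_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::V(g)$name
  ind <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (at in setdiff(igraph::vertex_attr_names(g), c("name", "id"))) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v)) v[v == ""] <- NA_character_
    if (is.numeric(v)) v[is.nan(v)] <- NA_real_
    ind[[at]] <- v
  }
  el <- igraph::as_data_frame(g, what = "edges")
  ind$father <- NA_character_
  ind$mother <- NA_character_
  if (nrow(el)) {
    fa <- el[el$role == "father", ]
    mo <- el[el$role == "mother", ]
    ind$father[match(fa$to, ind$id)] <- fa$from
    ind$mother[match(mo$to, ind$id)] <- mo$from
  }
  if ("sampled" %in% names(ind)) ind$sampled <- as.logical(ind$sampled)
  if ("generation" %in% names(ind)) ind$generation <- as.integer(ind$generation)
  pedigree(ind)
}

#' Test two pedigrees for structural equivalence
#'
#' Graph isomorphism on the parent-link graphs (VF2), with vertices
#' coloured by sex and sampling status and edges by parental role, so
#' that a reconstructed pedigree matches the truth exactly up to
#' relabelling of individuals that are genuinely indistinguishable from
#' the observations.
#'
#' @param ped_a,ped_b Pedigrees.
#' @return `TRUE` or `FALSE`.
#' @export
pedigree_isomorphic <- function(ped_a, ped_b) {
  prep <- function(ped) {
    g <- pedigree_graph(ped)
    sex_col <- match(igraph::V(g)$sex, c("male", "female", "unknown"))
    samp <- as.integer(as.logical(igraph::V(g)$sampled))
    igraph::V(g)$color <- sex_col * 2L + samp
    igraph::E(g)$color <- match(igraph::E(g)$role, c("father", "mother"))
    g
  }
  ga <- prep(ped_a); gb <- prep(ped_b)
  if (igraph::vcount(ga) != igraph::vcount(gb) ||
      igraph::ecount(ga) != igraph::ecount(gb)) return(FALSE)
  igraph::isomorphic(ga, gb, method = "vf2",
                     vertex.color1 = igraph::V(ga)$color,
                     vertex.color2 = igraph::V(gb)$color,
                     edge.color1 = igraph::E(ga)$color,
                     edge.color2 = igraph::E(gb)$color)
}
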