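#' Load a curated pathway gene-set collection
#'
#' The JSON schema is
#' `{"pathways": {"MAPK": {"nodes": {"NGF": ["NGF"], ...}}}}`: each pathway
#' is a set of diagram nodes, each node a list of member gene symbols. The
#' package bundles a best-effort curation of the MAPK, PI3K-AKT and
#' cell-cycle overlay diagrams (see
#' `system.file("extdata", "pathway_sets.json", package = "rbdge")`).
#'
#' @param file path to a gene-set JSON; default the bundled collection.
#' @param universe optional character vector of panel genes; member genes
#'   absent from it are reported via a warning (not an error) and kept.
#' @return A `rbdge_gene_sets` list: `pathways` (pathway -> node -> genes)
#'   and `universe`.
#' @export
load_gene_sets <- function(file = system.file("extdata", "pathway_sets.json",
                                              package = "rbdge"),
                           universe = NULL) {
  parsed <- tryCatch(jsonlite::read_json(file),
                     error = function(e) stop("gene-set parse error: ",
                                              conditionMessage(e)))
  if (is.null(parsed$pathways)) stop("gene-set JSON lacks a 'pathways' object")
  pathways <- lapply(parsed$pathways, function(pw) {
    nodes <- pw$nodes
    if (is.null(nodes)) return(list())
    if (anyDuplicated(names(nodes))) stop("duplicate node names in pathway")
    lapply(nodes, function(g) as.character(unlist(g)))
  })
  if (!is.null(universe)) {
    all_members <- unique(unlist(pathways, use.names = FALSE))
    missing <- setdiff(all_members, universe)
    if (length(missing) > 0) {
      warning("gene-set members absent from universe: ",
              paste(utils::head(missing, 10), collapse = ", "),
              if (length(missing) > 10) ", ...")
    }
  }
  structure(list(pathways = pathways, universe = universe),
            class = "rbdge_gene_sets")
}

# all genes referenced by the bundled collection (panel construction helper)
pathway_universe_genes <- function() {
  sets <- load_gene_sets()
  sort(unique(unlist(sets$pathways, use.names = FALSE)))
}

#' Ternary pathway-node states from differential expression results
#'
#' Maps gene-level differential expression onto diagram nodes: for each node
#' the significant member genes are tallied as up (log2 fold change > 0,
#' i.e. higher in URB) or down; a node is `+1` when up-votes exceed
#' down-votes, `-1` in the opposite case, `0` on a tie or when no member is
#' significant — the red/green/neutral coloring of the overlay figures.
#'
#' @param de a [run_de()] result (data frame with `gene`, `log2_fc`,
#'   `significant`).
#' @param sets a [load_gene_sets()] collection.
#' @return A data frame with one row per (pathway, node): `state` in
#'   `{-1, 0, 1}` and the supporting tallies `n_up`, `n_down`, `n_ns`.
#' @export
node_states <- function(de, sets) {
  stopifnot(inherits(sets, "rbdge_gene_sets"))
  de <- as.data.frame(de)
  sig_up <- de$gene[de$significant & de$log2_fc > 0]
  sig_down <- de$gene[de$significant & de$log2_fc < 0]
  rows <- list()
  for (pw in names(sets$pathways)) {
    nodes <- sets$pathways[[pw]]
    for (nd in names(nodes)) {
      members <- nodes[[nd]]
      n_up <- sum(members %in% sig_up)
      n_down <- sum(members %in% sig_down)
      n_ns <- length(intersect(members, de$gene)) - n_up - n_down
      state <- if (n_up > n_down) 1L else if (n_down > n_up) -1L else 0L
      rows[[length(rows) + 1]] <- data.frame(
        pathway = pw, node = nd, state = state,
        n_up = n_up, n_down = n_down, n_ns = n_ns,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of seeing at least the observed
#' overlap between a gene set and the significant genes, given the panel
#' universe. This is a deliberately simple stand-in for gene set enrichment:
#' no ranking statistic or permutation scheme is assumed.
#'
#' @param significant_genes character vector of significant genes.
#' @param node_genes character vector, the gene set (must lie in `universe`).
#' @param universe character vector of all testable panel genes.
#' @return One-sided p-value for over-representation.
#' @export
ora_test <- function(significant_genes, node_genes, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(node_genes %in% universe)) {
    stop("node genes must be a subset of the universe")
  }
  significant_genes <- intersect(significant_genes, universe)
  k <- length(intersect(significant_genes, node_genes))
  stats::phyper(k - 1, length(significant_genes),
                length(universe) - length(significant_genes),
                length(node_genes), lower.tail = FALSE)
}

#' Over-representation across all pathway nodes
#'
#' @param de a [run_de()] result.
#' @param sets a [load_gene_sets()] collection.
#' @param universe panel genes tested for differential expression; defaults
#'   to the genes present in `de`.
#' @return `node_states(de, sets)` augmented with an `ora_p` column
#'   (hypergeometric, members restricted to the universe).
#' @export
pathway_overlay <- function(de, sets, universe = de$gene) {
  st <- node_states(de, sets)
  sig <- de$gene[de$significant]
  st$ora_p <- vapply(seq_len(nrow(st)), function(i) {
    members <- intersect(sets$pathways[[st$pathway[i]]][[st$node[i]]],
                         universe)
    if (length(members) == 0) return(1)
    ora_test(sig, members, universe)
  }, numeric(1))
  st
}
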