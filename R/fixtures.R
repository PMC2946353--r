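# Packaged toy ontologies and synthetic data generators, so every layout and
# mapping operation is demonstrable and testable without any download.

#' Toy tree ontology G1
#'
#' A small pure tree with eight leaf pathways and five non-leaf categories:
#' root `R` over categories `A`, `B`, `C`; `A` holds subcategory `AA` plus
#' leaves `A1`, `A2`; `AA` holds `AA1`, `AA2`; `B` and `C` hold two leaves
#' each.  Twelve edges, no multiple inheritance.
#'
#' @return An `ontology_graph`.
#' @export
make_g1 <- function() {
  ontology_graph(tibble::tibble(
    parent = c("R", "R", "R", "A", "A", "A", "AA", "AA", "B", "B", "C", "C"),
    child = c("A", "B", "C", "AA", "A1", "A2", "AA1", "AA2", "B1", "B2",
              "C1", "C2")))
}

#' Toy DAG ontology G2
#'
#' G1 plus four non-tree edges making four terms multi-parented:
#' `C -> AA1` and `C -> AA2` (so category `C` is the minor parent of both
#' `AA1` and `AA2`), completed by the synthetic edges `B -> C1` and
#' `A -> B1` so that orbits land on more than one layer.  The G1 edges are
#' listed first, so under the first-listed major-parent rule the tree
#' structure of G1 is preserved and the four added edges are exactly the
#' non-tree edges.
#'
#' @return An `ontology_graph`.
#' @export
make_g2 <- function() {
  g1 <- make_g1()
  ontology_graph(dplyr::bind_rows(
    g1$edges,
    tibble::tibble(parent = c("C", "C", "B", "A"),
                   child = c("AA1", "AA2", "C1", "B1"))))
}

#' Generate a synthetic gene expression matrix annotated to G2
#'
#' Genes are assigned uniformly at random to the eight leaf pathways of G2;
#' baseline values are i.i.d. Normal(`mu0`, `sigma0`) on a log2-like
#' intensity scale; designated nodes receive additive shifts in designated
#' conditions (a shift on a category applies to all genes in its aggregated
#' set).  Fully reproducible from `seed`.
#'
#' @param n_genes Number of genes (> 0).
#' @param conditions Ordered condition labels; default a 7-point time series
#'   `t1..t7`.
#' @param effects `NULL`, or a data frame with columns `node`, `condition`,
#'   `shift` giving additive effects.
#' @param seed Integer seed.
#' @param mu0,sigma0 Baseline mean and standard deviation.
#' @return List with `expr` (tibble `gene` + conditions), `annotation`
#'   (tibble `node`, `gene`) and `graph` (the G2 `ontology_graph`).
#' @examples
#' sim <- synth_expression(40, conditions = c("ctrl", "trt"),
#'   effects = data.frame(node = "C1", condition = "trt", shift = 2))
#' @export
synth_expression <- function(n_genes, conditions = paste0("t", 1:7),
                             effects = NULL, seed = 1, mu0 = 8, sigma0 = 0.5) {
  stopifnot(n_genes > 0, length(conditions) >= 1)
  g2 <- make_g2()
  tree <- extract_spanning_tree(g2)
  leaves <- sort(tree$nodes$node[tree$nodes$is_leaf])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  annotation <- tibble::tibble(
    node = sample(leaves, n_genes, replace = TRUE), gene = genes)
  vals <- matrix(stats::rnorm(n_genes * length(conditions), mu0, sigma0),
                 nrow = n_genes, dimnames = list(genes, conditions))
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    unknown <- setdiff(effects$node, tree$nodes$node)
    if (length(unknown) > 0) {
      stop("effect spec names unknown node(s): ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    bad_cond <- setdiff(effects$condition, conditions)
    if (length(bad_cond) > 0) {
      stop("effect spec names unknown condition(s): ",
           paste(unique(bad_cond), collapse = ", "), call. = FALSE)
    }
    sets <- aggregate_gene_sets(annotation, tree)
    for (i in seq_len(nrow(effects))) {
      gi <- sets[[effects$node[i]]]
      vals[gi, effects$condition[i]] <-
        vals[gi, effects$condition[i]] + effects$shift[i]
    }
  }
  expr <- dplyr::bind_cols(tibble::tibble(gene = genes),
                           tibble::as_tibble(as.data.frame(vals)))
  list(expr = expr, annotation = annotation, graph = g2)
}

#' Generate a synthetic typed pathway graph
#'
#' `kind = "cycle"` emulates a metabolic cycle: `n` metabolites in a ring,
#' with `ceiling(n/2)` protein complexes each catalyzing one ring reaction
#' (linked to its two substrate metabolites) and carrying one RNA and one
#' DNA beneath it.  `kind = "signaling"` emulates a signaling hub: one
#' metabolite regulating `n` proteins, each with its RNA and DNA.
#'
#' @param kind `"cycle"` or `"signaling"`.
#' @param n Ring size / number of regulated proteins (>= 3).
#' @return A `pathway_graph`.
#' @export
synth_pathway <- function(kind = c("cycle", "signaling"), n = 6) {
  kind <- match.arg(kind)
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (kind == "cycle") {
    mets <- sprintf("M%02d", seq_len(n))
    np <- ceiling(n / 2)
    prots <- sprintf("P%02d", seq_len(np))
    rnas <- sprintf("R%02d", seq_len(np))
    dnas <- sprintf("D%02d", seq_len(np))
    ring <- tibble::tibble(source = mets, target = c(mets[-1], mets[1]),
                           interaction = "conversion")
    # protein j catalyzes the reaction leaving metabolite 2j-1
    sub1 <- mets[pmin(2 * seq_len(np) - 1, n)]
    sub2 <- mets[ifelse(2 * seq_len(np) %% n == 0, n, 2 * seq_len(np) %% n)]
    catal <- tibble::tibble(source = rep(prots, 2),
                            target = c(sub1, sub2),
                            interaction = "catalysis")
    central <- tibble::tibble(
      source = c(dnas, rnas), target = c(rnas, prots),
      interaction = rep(c("transcription", "translation"), each = np))
    nodes <- tibble::tibble(
      id = c(mets, prots, rnas, dnas),
      type = rep(c("metabolite", "polypeptide", "RNA", "DNA"),
                 c(n, np, np, np)))
    pathway_graph(nodes, dplyr::bind_rows(ring, catal, central))
  } else {
    hub <- "HUB"
    prots <- sprintf("P%02d", seq_len(n))
    rnas <- sprintf("R%02d", seq_len(n))
    dnas <- sprintf("D%02d", seq_len(n))
    edges <- dplyr::bind_rows(
      tibble::tibble(source = hub, target = prots, interaction = "regulation"),
      tibble::tibble(source = dnas, target = rnas,
                     interaction = "transcription"),
      tibble::tibble(source = rnas, target = prots,
                     interaction = "translation"))
    nodes <- tibble::tibble(
      id = c(hub, prots, rnas, dnas),
      type = rep(c("metabolite", "polypeptide", "RNA", "DNA"),
                 c(1, n, n, n)))
    pathway_graph(nodes, edges)
  }
}

#' Write every packaged fixture to a directory
#'
#' Emits `g1.tsv`, `g2.tsv`, `expr.csv`, `annotation.tsv` and `pathway.tsv`
#' in the module file formats, ready for the command-line interface.
#'
#' @param dir Target directory (created if needed).
#' @param n_genes,conditions,effects,seed Passed to [synth_expression()];
#'   the default adds a +2 shift on pathway `C1` in the last condition.
#' @return Character vector of written paths, invisibly.
#' @export
write_fixtures <- function(dir, n_genes = 200,
                           conditions = paste0("t", 1:7),
                           effects = NULL, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(effects)) {
    effects <- tibble::tibble(node = "C1",
                              condition = conditions[length(conditions)],
                              shift = 2)
  }
  paths <- file.path(dir, c("g1.tsv", "g2.tsv", "expr.csv", "annotation.tsv",
                            "pathway.tsv"))
  write_edge_list(make_g1(), paths[1])
  write_edge_list(make_g2(), paths[2])
  sim <- synth_expression(n_genes, conditions, effects, seed = seed)
  utils::write.csv(as.data.frame(sim$expr), paths[3], row.names = FALSE)
  utils::write.table(as.data.frame(sim$annotation), paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  pg <- synth_pathway("cycle", 6)
  ty <- stats::setNames(pg$nodes$type, pg$nodes$id)
  net <- tibble::tibble(source = pg$edges$source, target = pg$edges$target,
                        source_type = unname(ty[pg$edges$source]),
                        target_type = unname(ty[pg$edges$target]),
                        interaction = pg$edges$interaction)
  utils::write.table(as.data.frame(net), paths[5], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
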