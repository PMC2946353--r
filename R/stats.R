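# Mapping gene-level experimental values onto ontology terms: gene-set
# aggregation up the spanning tree, ensemble statistics (mean/median/CoV),
# differential-expression classification, Fisher overrepresentation, and the
# statistic-to-geometry style maps (color, height, transparency, frames).

#' Read an expression CSV (genes x conditions)
#'
#' First column `gene`, remaining columns conditions; missing values are
#' empty cells or `NA`.
#'
#' @param path CSV path.
#' @return Tibble with a `gene` character column and one numeric column per
#'   condition, in file order.
#' @export
read_expression_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (names(df)[1] != "gene") names(df)[1] <- "gene"
  df$gene <- as.character(df$gene)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene id(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a node-to-gene annotation TSV
#'
#' Two tab-separated columns `node_id<TAB>gene_id`, `#` comments allowed.
#'
#' @param path TSV path.
#' @return Tibble with columns `node`, `gene`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, col.names = c("node", "gene"))
  if (identical(df[1, 1], "node_id")) df <- df[-1, , drop = FALSE]
  tibble::as_tibble(df)
}

#' Aggregate annotated gene sets up the spanning tree
#'
#' Every region of the sunburst represents a group of genes: a node's set is
#' its direct annotations unioned with the sets of its tree children
#' (a gene shared by two child pathways counts once).  Propagation follows
#' tree edges only.
#'
#' @param annotation Tibble with columns `node`, `gene` (direct annotations),
#'   or a named list of character vectors.
#' @param tree A `spanning_tree`.
#' @return Named list: node id to character vector of gene ids (possibly
#'   empty), one entry per tree node.
#' @export
aggregate_gene_sets <- function(annotation, tree) {
  if (is.data.frame(annotation)) {
    direct <- split(as.character(annotation$gene), annotation$node)
  } else {
    direct <- lapply(annotation, as.character)
  }
  unknown <- setdiff(names(direct), tree$nodes$node)
  if (length(unknown) > 0) {
    stop("annotation to unknown node id(s): ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  children <- tree_children(tree)
  sets <- stats::setNames(vector("list", nrow(tree$nodes)), tree$nodes$node)
  for (id in tree$nodes$node[order(-tree$nodes$depth)]) {
    own <- direct[[id]]
    kid_sets <- sets[children[[id]]]
    # as.character() keeps empty sets as character(0) (a bare NULL would
    # delete the list element)
    sets[[id]] <- as.character(
      sort(unique(c(own, unlist(kid_sets, use.names = FALSE)))))
  }
  sets
}

#' Coefficient of variation (population form)
#'
#' `CoV = sigma / mu` with the population standard deviation
#' `sigma = sqrt(sum((x - mu)^2) / N)`.  Undefined when the mean is zero (or
#' when no finite values remain): returns `NA` with a warning rather than
#' taking absolute values.  Missing values are dropped pairwise.
#'
#' @param x Numeric vector.
#' @return A single numeric CoV, or `NA_real_` if undefined.
#' @examples
#' compute_cov(c(2, 4, 6))  # sqrt(8/3)/4 ~= 0.408
#' @export
compute_cov <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mu <- mean(x)
  if (mu == 0) {
    warning("CoV undefined for zero mean; returning NA", call. = FALSE)
    return(NA_real_)
  }
  sqrt(sum((x - mu)^2) / length(x)) / mu
}

#' Classify genes as up/down/unchanged between two conditions
#'
#' A gene is differentially expressed when its value changes by strictly more
#' than the threshold (`|treatment - control| > threshold`); it is
#' down-regulated if the treatment value is lower, otherwise up-regulated.
#' The default threshold of 0.7 assumes values on a log scale so that the
#' absolute difference reads as a fold change.  Missing values classify as
#' `unchanged`.
#'
#' @param control,treatment Numeric vectors of equal length.
#' @param threshold Positive change threshold (default 0.7).
#' @param metric `"difference"` (default) compares `treatment - control`;
#'   `"ratio"` compares `log2(treatment / control)` for users supplying
#'   linear-scale values.
#' @return Factor with levels `up`, `down`, `unchanged`.
#' @export
classify_differential <- function(control, treatment, threshold = 0.7,
                                  metric = c("difference", "ratio")) {
  metric <- match.arg(metric)
  stopifnot(length(control) == length(treatment), threshold > 0)
  delta <- switch(metric,
                  difference = treatment - control,
                  ratio = log2(treatment / control))
  cls <- rep("unchanged", length(delta))
  de <- !is.na(delta) & abs(delta) > threshold
  cls[de & delta > 0] <- "up"
  cls[de & delta < 0] <- "down"
  factor(cls, levels = c("up", "down", "unchanged"))
}

#' One-sided Fisher overrepresentation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' `k = |selected intersect node_genes|` annotated genes when `|selected|`
#' genes are drawn from a universe containing `|node_genes|` successes —
#' the usual one-sided Fisher's exact test for term enrichment in a gene
#' list.
#'
#' @param selected Character vector: the gene list of interest (subset of
#'   `universe`).
#' @param node_genes Character vector: the term's gene set (subset of
#'   `universe`).
#' @param universe Character vector of all considered genes.
#' @return A p-value in `(0, 1]`.
#' @examples
#' fisher_overrepresentation(letters[1:5], letters[c(1:4, 6)], letters[1:10])
#' @export
fisher_overrepresentation <- function(selected, node_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  selected <- unique(selected)
  node_genes <- unique(node_genes)
  if (length(setdiff(selected, universe)) > 0 ||
      length(setdiff(node_genes, universe)) > 0) {
    stop("selected and node gene sets must be subsets of the universe",
         call. = FALSE)
  }
  k <- length(intersect(selected, node_genes))
  m <- length(node_genes)
  n <- length(universe) - m
  s <- length(selected)
  stats::phyper(k - 1, m, n, s, lower.tail = FALSE)
}

#' Per-node ensemble statistics over an expression matrix
#'
#' For every tree node, summarises its aggregated gene set: per-condition
#' mean and median (over the genes observed in the matrix), the mean
#' coefficient of variation of its genes across conditions, and — when a
#' control/treatment pair is given — up/down/total differential counts.
#' Genes annotated but absent from the matrix are ignored (their count is in
#' `n_missing`).
#'
#' @param expr Expression tibble from [read_expression_csv()] (column `gene`
#'   plus one numeric column per condition).
#' @param gene_sets Named list from [aggregate_gene_sets()].
#' @param control,treatment Optional condition labels for differential
#'   counts.
#' @param threshold,metric Passed to [classify_differential()].
#' @return Tibble with one row per (node, condition): `node`, `condition`,
#'   `n_genes`, `n_missing`, `mean`, `median`, `cov`, and per-pair columns
#'   `n_up`, `n_down`, `n_de` (repeated across conditions of a node).
#' @export
node_stats <- function(expr, gene_sets, control = NULL, treatment = NULL,
                       threshold = 0.7, metric = "difference") {
  conditions <- setdiff(names(expr), "gene")
  mat <- as.matrix(expr[, conditions, drop = FALSE])
  rownames(mat) <- expr$gene
  purrr::imap_dfr(gene_sets, function(genes, node) {
    present <- intersect(genes, expr$gene)
    sub <- mat[present, , drop = FALSE]
    cov_mean <- if (length(present) > 0) {
      covs <- suppressWarnings(apply(sub, 1, compute_cov))
      if (all(is.na(covs))) NA_real_ else mean(covs, na.rm = TRUE)
    } else NA_real_
    base <- tibble::tibble(
      node = node, condition = conditions,
      n_genes = length(genes), n_missing = length(genes) - length(present),
      mean = if (length(present) > 0) unname(colMeans(sub, na.rm = TRUE)) else
        rep(NA_real_, length(conditions)),
      median = if (length(present) > 0)
        unname(apply(sub, 2, stats::median, na.rm = TRUE)) else
        rep(NA_real_, length(conditions)),
      cov = cov_mean)
    base$mean[is.nan(base$mean)] <- NA_real_
    if (!is.null(control) && !is.null(treatment)) {
      for (cn in c(control, treatment)) {
        if (!cn %in% conditions) stop("unknown condition: ", cn, call. = FALSE)
      }
      cls <- if (length(present) > 0) {
        classify_differential(sub[, control], sub[, treatment],
                              threshold = threshold, metric = metric)
      } else factor(character(0), levels = c("up", "down", "unchanged"))
      base$n_up <- sum(cls == "up")
      base$n_down <- sum(cls == "down")
      base$n_de <- base$n_up + base$n_down
    }
    base
  })
}

#' Per-node Fisher overrepresentation of a gene list
#'
#' @param gene_sets Named list from [aggregate_gene_sets()].
#' @param selected Gene list of interest.
#' @param universe Gene universe; defaults to the union of all node sets.
#' @return Tibble `node`, `n_genes`, `n_overlap`, `p_value`, sorted by
#'   `p_value`.
#' @export
node_fisher <- function(gene_sets, selected, universe = NULL) {
  if (is.null(universe)) universe <- unique(unlist(gene_sets, use.names = FALSE))
  selected <- intersect(unique(selected), universe)
  purrr::imap_dfr(gene_sets, function(genes, node) {
    genes <- intersect(genes, universe)
    tibble::tibble(node = node, n_genes = length(genes),
                   n_overlap = length(intersect(selected, genes)),
                   p_value = fisher_overrepresentation(selected, genes, universe))
  }) |> dplyr::arrange(.data$p_value, .data$node)
}

# green -> yellow -> red ramp on t in [0,1]
ramp_gyr <- function(t) {
  r <- pmin(1, 2 * t)
  g <- pmin(1, 2 * (1 - t))
  cbind(r = r, g = g, b = 0)
}

# green (-1) -> white (0) -> red (+1) diverging ramp on t in [-1,1]
ramp_gwr <- function(t) {
  r <- ifelse(t >= 0, 1, 1 + t)
  g <- ifelse(t >= 0, 1 - t, 1)
  b <- 1 - abs(t)
  cbind(r = r, g = g, b = b)
}

#' Map a per-node statistic onto region color or height
#'
#' Linear map of the chosen statistic onto a green-yellow-red ramp (`color`)
#' or onto `[0, Hmax]` (`height`).  Nodes with a missing statistic are
#' rendered grey and flat.  The range defaults to the observed min/max but
#' can be fixed for cross-frame comparability (the same value then always
#' gets the same color in every animation frame).
#'
#' @param stats_tbl Tibble with a `node` column and the statistic column.
#' @param stat Name of the statistic column (e.g. `"mean"`, `"cov"`).
#' @param encoding `"color"`, `"height"`, or `"both"`.
#' @param range Length-2 numeric range for the linear map; default data
#'   min/max.
#' @param Hmax Height at range max (layout units).
#' @param frame Optional frame label stored in the style map.
#' @return A style map tibble: `node`, `r`, `g`, `b`, `a`, `height`,
#'   `visible`, `frame`.
#' @export
style_by_value <- function(stats_tbl, stat = "mean",
                           encoding = c("color", "height", "both"),
                           range = NULL, Hmax = 30, frame = NA_character_) {
  encoding <- match.arg(encoding)
  if (!stat %in% names(stats_tbl)) {
    stop("statistic column '", stat, "' not present", call. = FALSE)
  }
  v <- stats_tbl[[stat]]
  ok <- is.finite(v)
  if (is.null(range)) {
    range <- if (any(ok)) range(v[ok]) else c(0, 1)
  }
  if (range[1] == range[2]) {
    warning("degenerate statistic range; all nodes mapped to mid-palette",
            call. = FALSE)
    t <- ifelse(ok, 0.5, NA_real_)
  } else {
    t <- ifelse(ok, pmin(1, pmax(0, (v - range[1]) / (range[2] - range[1]))),
                NA_real_)
  }
  col <- ramp_gyr(ifelse(is.na(t), 0.5, t))
  st <- tibble::tibble(
    node = stats_tbl$node,
    r = ifelse(ok, col[, "r"], 0.6),
    g = ifelse(ok, col[, "g"], 0.6),
    b = ifelse(ok, col[, "b"], 0.6),
    a = 1,
    height = ifelse(ok, t * Hmax, 0),
    visible = TRUE,
    frame = frame)
  if (encoding == "color") st$height <- ifelse(ok, NA_real_, 0)
  if (encoding == "height") { st$r <- 0.6; st$g <- 0.6; st$b <- 0.6 }
  st
}

#' Differential view: DE counts to height, up/down ratio to color
#'
#' Encodes each region's differential-expression summary: height is
#' `H0 * log2(n_de + 1)` (the logarithm tames the large dynamic range of
#' cumulative counts in top categories), and color is the balance
#' `s = log2((n_up + 1) / (n_down + 1))` clipped to `[-3, 3]` on a
#' green-white-red diverging ramp — reddish regions are mainly up-regulated,
#' greenish mainly down.  Regions with fewer than `min_de` DE genes are
#' non-interesting and left fully transparent so interesting ones stand out.
#'
#' @param stats_tbl Tibble with `node`, `n_up`, `n_down`, `n_de` (one row per
#'   node; extra per-condition rows are deduplicated).
#' @param min_de Minimum DE-gene count for a region to stay visible.
#' @param H0 Height unit.
#' @param frame Optional frame label.
#' @return A style map tibble (see [style_by_value()]).
#' @export
style_differential_view <- function(stats_tbl, min_de = 5, H0 = 5,
                                    frame = NA_character_) {
  d <- dplyr::distinct(stats_tbl, .data$node, .data$n_up, .data$n_down,
                       .data$n_de)
  s <- pmin(3, pmax(-3, log2((d$n_up + 1) / (d$n_down + 1))))
  col <- ramp_gwr(s / 3)
  tibble::tibble(node = d$node,
                 r = col[, "r"], g = col[, "g"], b = col[, "b"], a = 1,
                 height = H0 * log2(d$n_de + 1),
                 visible = d$n_de >= min_de,
                 frame = frame)
}

#' Build one style frame per condition for animation
#'
#' A time series with `k` conditions becomes an animation of `k` frames, one
#' per matrix column in column order; `conditions` can subset or rearrange
#' them.  All frames share one color range (the default is the min/max over
#' the chosen statistic across all chosen conditions) so colors are
#' comparable across frames.
#'
#' @param expr Expression tibble.
#' @param gene_sets Named list from [aggregate_gene_sets()].
#' @param stat Per-condition statistic to encode: `"mean"` or `"median"`.
#' @param conditions Optional character vector reordering/subsetting the
#'   matrix conditions.
#' @param range,Hmax,encoding Passed to [style_by_value()].
#' @return Named list of style maps, one per frame, in frame order.
#' @export
build_animation_frames <- function(expr, gene_sets, stat = c("mean", "median"),
                                   conditions = NULL, range = NULL,
                                   Hmax = 30, encoding = "color") {
  stat <- match.arg(stat)
  all_cond <- setdiff(names(expr), "gene")
  if (length(all_cond) == 0) stop("expression matrix has no conditions",
                                  call. = FALSE)
  if (is.null(conditions)) conditions <- all_cond
  unknown <- setdiff(conditions, all_cond)
  if (length(unknown) > 0) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  st <- node_stats(expr, gene_sets)
  st <- st[st$condition %in% conditions, , drop = FALSE]
  if (is.null(range)) {
    v <- st[[stat]]
    range <- if (any(is.finite(v))) range(v[is.finite(v)]) else c(0, 1)
  }
  frames <- lapply(conditions, function(cn) {
    style_by_value(st[st$condition == cn, , drop = FALSE], stat = stat,
                   encoding = encoding, range = range, Hmax = Hmax, frame = cn)
  })
  stats::setNames(frames, conditions)
}

#' Dump the expression of one node's genes to CSV
#'
#' Writes the genes-by-conditions slice for a selected region, the plain-file
#' stand-in for a linked spreadsheet view.
#'
#' @param expr Expression tibble.
#' @param gene_sets Named list from [aggregate_gene_sets()].
#' @param node Node id.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_node_genes_csv <- function(expr, gene_sets, node, path) {
  if (!node %in% names(gene_sets)) stop("unknown node id: ", node, call. = FALSE)
  slice <- expr[expr$gene %in% gene_sets[[node]], , drop = FALSE]
  utils::write.csv(as.data.frame(slice), path, row.names = FALSE)
  invisible(slice)
}
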