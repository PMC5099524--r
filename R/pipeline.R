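#' Density grid for proportional thresholding
#'
#' Inclusive arithmetic grid `lo, lo + step, ..., hi`, with the count
#' computed in integer arithmetic so that binary floating point cannot drop
#' the endpoint: `0.10:0.60:0.05` always yields exactly 11 densities.
#'
#' @param lo,hi grid endpoints, `0 < lo <= hi <= 1`.
#' @param step positive increment; `hi - lo` must be a whole multiple of it
#'   (to 1 part in 1e6).
#' @return A numeric vector of densities.
#' @export
density_grid <- function(lo = 0.10, hi = 0.60, step = 0.05) {
  stopifnot(lo > 0, lo <= hi, hi <= 1, step > 0)
  n <- round((hi - lo) / step)
  if (abs(lo + n * step - hi) > 1e-6) {
    stop("grid step does not evenly divide [lo, hi]")
  }
  lo + (0:n) * step
}

#' Threshold sweep of binary metrics
#'
#' Binarizes the network at every density of the grid, evaluates the
#' requested binary metrics, and integrates each node's value-vs-density
#' curve with the trapezoidal rule to get one threshold-independent scalar
#' per node and metric.
#'
#' @param net a [weighted_network()] object.
#' @param metrics subset of `c("dc", "bc", "eff")`.
#' @param grid densities from [density_grid()].
#' @return A list of class `hs_sweep`: `curves` (tibble `node`, `metric`,
#'   `density`, `value`) and `integrated` (tibble `node`, `metric`,
#'   `integrated`).
#' @export
metric_threshold_sweep <- function(net, metrics = c("dc", "bc", "eff"),
                                   grid = density_grid()) {
  stopifnot(inherits(net, "hs_network"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  fns <- list(dc = degree_centrality, bc = betweenness_centrality,
              eff = local_efficiency)
  curves <- purrr::map_dfr(grid, function(d) {
    bn <- threshold_proportional(net, d)
    purrr::map_dfr(metrics, function(m) {
      v <- fns[[m]](bn)
      tibble::tibble(node = v$node, metric = m, density = d,
                     value = as.numeric(v[[2]]))
    })
  })
  integrated <- curves |>
    dplyr::group_by(.data$node, .data$metric) |>
    dplyr::arrange(.data$density, .by_group = TRUE) |>
    dplyr::summarise(integrated = trapezoid(.data$density, .data$value),
                     .groups = "drop")
  structure(list(curves = curves, integrated = integrated,
                 grid = grid), class = "hs_sweep")
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' @export
print.hs_sweep <- function(x, ...) {
  cat("<hs_sweep> ", length(unique(x$curves$metric)), " metrics at ",
      length(x$grid), " densities, ", length(unique(x$curves$node)),
      " nodes\n", sep = "")
  invisible(x)
}

#' Identify hubs of a metric distribution
#'
#' Hubs are nodes whose metric value strictly exceeds the distribution mean
#' by more than one sample standard deviation. A zero-variance distribution
#' yields no hubs.
#'
#' @param values tibble with `node` and one value column (any of the metric
#'   tibbles produced by this package), or a named numeric vector.
#' @param metric_name label for the report (defaults to the value column
#'   name).
#' @return A list of class `hs_hubs`: `metric`, `mean`, `sd`, `cutoff` and
#'   the character vector `hubs`.
#' @export
identify_hubs <- function(values, metric_name = NULL) {
  if (is.numeric(values)) {
    v <- unname(values)
    nodes <- names(values)
    if (is.null(metric_name)) metric_name <- "metric"
  } else {
    stopifnot(ncol(values) >= 2L)
    v <- as.numeric(values[[2]])
    nodes <- values$node
    if (is.null(metric_name)) metric_name <- names(values)[2]
  }
  if (length(v) < 2L) stop("need at least 2 nodes")
  mu <- mean(v)
  s <- sd(v)
  cutoff <- mu + s
  structure(list(metric = metric_name, mean = mu, sd = s, cutoff = cutoff,
                 hubs = nodes[v > cutoff]),
            class = "hs_hubs")
}

#' @export
print.hs_hubs <- function(x, ...) {
  cat("<hs_hubs> ", x$metric, ": ", length(x$hubs),
      " hub(s) above ", format(x$cutoff, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Pearson correlation between two metric vectors
#'
#' Bivariate Pearson correlation with a two-sided p-value from the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param a,b metric tibbles (`node` + value column) over the same nodes, or
#'   plain numeric vectors of equal length.
#' @return A tibble with `r`, `p`, `n` and `significant` (at `p < 0.05`).
#' @export
correlate_metrics <- function(a, b) {
  va <- if (is.numeric(a)) a else as.numeric(a[[2]])
  vb <- if (is.numeric(b)) b else as.numeric(b[[2]])
  if (!is.numeric(a) && !is.numeric(b)) {
    stopifnot(identical(a$node, b$node))
  }
  n <- length(va)
  if (n != length(vb) || n < 3L) stop("need equal-length vectors, n >= 3")
  if (sd(va) == 0 || sd(vb) == 0) stop("zero-variance metric vector")
  r <- cor(va, vb)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(r = r, p = p, n = n, significant = p < 0.05)
}

#' @importFrom stats pt
NULL

#' Overlap between two hub reports
#'
#' @param a,b [identify_hubs()] reports over the same node universe.
#' @return A tibble with `count` (shared hubs), `n_a` and `fraction_of_a`
#'   (`count / n_a`, `NaN` when `a` has no hubs).
#' @export
hub_overlap <- function(a, b) {
  stopifnot(inherits(a, "hs_hubs"), inherits(b, "hs_hubs"))
  count <- length(intersect(a$hubs, b$hubs))
  tibble::tibble(count = count, n_a = length(a$hubs),
                 fraction_of_a = count / length(a$hubs))
}

#' Full scaffold-versus-graph-metrics analysis
#'
#' Runs the complete comparison workflow on one weighted network:
#' filtration, H1 persistence, both scaffolds and the nodal PSS; a binary
#' threshold sweep of DC/BC/Eff with trapezoidal integration; strength,
#' weighted BC and weighted local efficiency on the full matrix; Louvain
#' communities at `community_density` and the participation coefficient;
#' per-density correlations of PSS–DC, PSS–BC, PSS–Eff and the control pairs
#' DC–BC, DC–Eff, BC–Eff; single correlations of PSS against SC, weighted
#' BC, weighted Eff and PC; hub reports on PSS and the integrated DC/BC/Eff
#' with their overlaps against the PSS hubs.
#'
#' @param net a [weighted_network()] object.
#' @param grid density grid for the binary sweep.
#' @param community_density density at which communities are detected.
#' @param order_mode filtration order, see [weight_rank_filtration()].
#' @param open_policy open-class handling, see [compute_persistence()].
#' @param seed integer seed (Louvain node order).
#' @return A list of class `hs_analysis` with elements `config`, `barcode`,
#'   `scaffolds`, `pss`, `sweep`, `weighted` (tibble of SC/wt-BC/wt-Eff),
#'   `partition`, `pc`, `correlations` (tibble `pair`, `density`, `r`, `p`,
#'   `significant`), `hubs` (named list of reports) and `overlaps`.
#' @export
run_full_analysis <- function(net, grid = density_grid(),
                              community_density = 0.40,
                              order_mode = "signed-descending",
                              open_policy = "flag",
                              seed = 1L) {
  stopifnot(inherits(net, "hs_network"))
  flt <- weight_rank_filtration(net, order_mode = order_mode)
  barcode <- compute_persistence(flt, open_policy = open_policy)
  sc_p <- scaffold(barcode, "persistence")
  sc_f <- scaffold(barcode, "frequency")
  pss_tbl <- pss(sc_p)

  sweep <- metric_threshold_sweep(net, c("dc", "bc", "eff"), grid)
  wide <- function(d, m) {
    v <- sweep$curves[sweep$curves$density == d & sweep$curves$metric == m, ]
    v$value[match(net$labels, v$node)]
  }
  pss_v <- pss_tbl$pss[match(net$labels, pss_tbl$node)]

  sc_tbl <- strength_centrality(net)
  wbc_tbl <- weighted_betweenness(net)
  weff_tbl <- weighted_local_efficiency(net)
  weighted <- tibble::tibble(node = net$labels,
                             sc = sc_tbl$sc, wt_bc = wbc_tbl$wt_bc,
                             wt_eff = weff_tbl$wt_eff)

  bn_comm <- threshold_proportional(net, community_density)
  partition <- louvain_communities(bn_comm, seed = seed)
  pc_tbl <- participation_coefficient(bn_comm, partition)

  per_density_pairs <- list(
    c("pss", "dc"), c("pss", "bc"), c("pss", "eff"),
    c("dc", "bc"), c("dc", "eff"), c("bc", "eff"))
  vec_at <- function(name, d) if (name == "pss") pss_v else wide(d, name)
  safe_cor <- function(a, b) {
    # degenerate (zero-variance) metrics at some density yield an NA row
    # rather than aborting the bundle
    if (sd(a) == 0 || sd(b) == 0) {
      return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(a),
                            significant = NA))
    }
    correlate_metrics(a, b)
  }
  cor_pd <- purrr::map_dfr(grid, function(d) {
    purrr::map_dfr(per_density_pairs, function(pr) {
      ct <- safe_cor(vec_at(pr[1], d), vec_at(pr[2], d))
      tibble::tibble(pair = paste(toupper(pr[1]), "v", toupper(pr[2])),
                     density = d, r = ct$r, p = ct$p,
                     significant = ct$significant)
    })
  })
  single <- list(SC = weighted$sc, `WT-BC` = weighted$wt_bc,
                 `WT-EFF` = weighted$wt_eff,
                 PC = pc_tbl$pc[match(net$labels, pc_tbl$node)])
  cor_single <- purrr::imap_dfr(single, function(v, nm) {
    ct <- safe_cor(pss_v, v)
    tibble::tibble(pair = paste("PSS v", nm), density = NA_real_,
                   r = ct$r, p = ct$p, significant = ct$significant)
  })
  correlations <- dplyr::bind_rows(cor_pd, cor_single)

  integ <- function(m) {
    v <- sweep$integrated[sweep$integrated$metric == m, ]
    setNames(v$integrated[match(net$labels, v$node)], net$labels)
  }
  hubs <- list(
    pss = identify_hubs(setNames(pss_v, net$labels), "pss"),
    dc = identify_hubs(integ("dc"), "dc"),
    bc = identify_hubs(integ("bc"), "bc"),
    eff = identify_hubs(integ("eff"), "eff")
  )
  overlaps <- purrr::map_dfr(c("dc", "bc", "eff"), function(m) {
    ov <- hub_overlap(hubs$pss, hubs[[m]])
    tibble::tibble(pair = paste("pss v", m), count = ov$count,
                   n_pss_hubs = ov$n_a, fraction = ov$fraction_of_a)
  })

  structure(list(
    config = list(grid = grid, community_density = community_density,
                  order_mode = order_mode, open_policy = open_policy,
                  seed = seed, n_nodes = net$n_nodes),
    barcode = barcode, scaffolds = list(persistence = sc_p, frequency = sc_f),
    pss = pss_tbl, sweep = sweep, weighted = weighted,
    partition = partition, pc = pc_tbl,
    correlations = correlations, hubs = hubs, overlaps = overlaps
  ), class = "hs_analysis")
}

#' @export
print.hs_analysis <- function(x, ...) {
  cat("<hs_analysis> ", x$config$n_nodes, " nodes; ",
      nrow(x$barcode), " H1 classes; ",
      nrow(x$correlations), " correlations; ",
      length(x$hubs$pss$hubs), " PSS hubs\n", sep = "")
  invisible(x)
}

#' @export
glance.hs_analysis <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$config$n_nodes,
    n_classes = nrow(x$barcode),
    n_communities = attr(x$partition, "n_communities"),
    n_pss_hubs = length(x$hubs$pss$hubs),
    max_pss = max(x$pss$pss)
  )
}

#' Write a full-analysis report as structured text
#'
#' Deterministic `key=value` report: identical analyses serialize to
#' byte-identical files. Numbers are printed with 15 significant digits.
#'
#' @param x an [run_full_analysis()] result.
#' @param path destination file; omit to get the lines invisibly.
#' @return The report lines, invisibly.
#' @export
write_analysis_report <- function(x, path = NULL) {
  stopifnot(inherits(x, "hs_analysis"))
  num <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  lines <- c(
    "report=homscaffold full analysis",
    paste0("n_nodes=", x$config$n_nodes),
    paste0("seed=", x$config$seed),
    paste0("order_mode=", x$config$order_mode),
    paste0("open_policy=", x$config$open_policy),
    paste0("grid=", paste(num(x$config$grid), collapse = ",")),
    paste0("community_density=", num(x$config$community_density)),
    paste0("n_h1_classes=", nrow(x$barcode)),
    paste0("n_communities=", attr(x$partition, "n_communities")),
    paste0("barcode=", paste(sprintf("%d:%s", x$barcode$birth,
                                     ifelse(is.na(x$barcode$death), "inf",
                                            as.character(x$barcode$death))),
                             collapse = ";")),
    paste0("pss=", paste(sprintf("%s:%s", x$pss$node, num(x$pss$pss)),
                         collapse = ";")),
    paste0("correlation=", sprintf("%s@%s r=%s p=%s", x$correlations$pair,
                                   ifelse(is.na(x$correlations$density),
                                          "full", num(x$correlations$density)),
                                   num(x$correlations$r),
                                   num(x$correlations$p))),
    vapply(names(x$hubs), function(h) {
      paste0("hubs_", h, "=", paste(x$hubs[[h]]$hubs, collapse = ","))
    }, character(1)),
    paste0("overlap=", sprintf("%s %d/%d", x$overlaps$pair,
                               x$overlaps$count, x$overlaps$n_pss_hubs))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
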