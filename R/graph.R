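#' Build a cell-type interaction graph from a fitted model
#'
#' One node per type, sized by the total self-interaction strength (the
#' sum over ranges of the self-pair log coefficients), and one edge per
#' unordered pair of distinct types carrying the per-range coefficients
#' with their 95% intervals. `mode = "raw"` shows the inherent log
#' interaction coefficients; `mode = "adjusted"` adds the log base
#' intensities of the endpoint types (`adjust = "both"`, the default) or
#' their mean (`adjust = "one"`), giving the apparent interaction in
#' tissue. With `filter_insignificant = TRUE`, range-edges whose raw
#' coefficient interval contains 0 are dropped.
#'
#' @param model A fitted `mrss` model (with intervals when filtering).
#' @param mode `"raw"` or `"adjusted"`.
#' @param filter_insignificant Drop range-edges whose 95% CI covers 0.
#' @param adjust `"both"` or `"one"` endpoint base intensities (adjusted
#'   mode only).
#' @return An `interaction_graph`: `nodes` and `edges` tibbles plus
#'   display metadata.
#' @export
build_interaction_graph <- function(model, mode = c("raw", "adjusted"),
                                    filter_insignificant = FALSE,
                                    adjust = c("both", "one")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  tab <- tidy(model)
  deltas <- tab[tab$kind == "delta", ]
  if (filter_insignificant && all(is.na(deltas$ci_low)))
    stop("model carries no confidence intervals; fit it before filtering")
  self <- deltas[deltas$type_a == deltas$type_b, ]
  nodes <- self |>
    dplyr::group_by(type = .data$type_a) |>
    dplyr::summarise(self_strength = sum(.data$estimate), .groups = "drop")
  self_ranges <- self |>
    dplyr::transmute(type = .data$type_a, bin = .data$bin,
                     value = .data$estimate,
                     ci_low = .data$ci_low, ci_high = .data$ci_high)
  edges <- deltas[deltas$type_a != deltas$type_b, ] |>
    dplyr::transmute(type_a = .data$type_a, type_b = .data$type_b,
                     bin = .data$bin, value = .data$estimate,
                     ci_low = .data$ci_low, ci_high = .data$ci_high,
                     significant = !is.na(.data$ci_low) &
                       (.data$ci_low > 0 | .data$ci_high < 0))
  if (mode == "adjusted") {
    lb <- model$log_beta
    shift <- unname(switch(adjust,
                           both = lb[edges$type_a] + lb[edges$type_b],
                           one = (lb[edges$type_a] + lb[edges$type_b]) / 2))
    edges$value <- edges$value + shift
    edges$ci_low <- edges$ci_low + shift
    edges$ci_high <- edges$ci_high + shift
  }
  edges$sign <- ifelse(edges$value > 0, "positive", "negative")
  if (filter_insignificant) edges <- edges[edges$significant, ]
  structure(list(nodes = nodes, self_ranges = self_ranges, edges = edges,
                 mode = mode, adjust = adjust,
                 filtered = filter_insignificant,
                 type_set = model$type_set,
                 n_ranges = n_ranges(model$range_spec)),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction graph (%s%s): %d nodes, %d range-edges\n",
              x$mode, if (x$filtered) ", filtered" else "",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.interaction_graph <- function(x, ...) x$edges

#' Median interaction graph across models
#'
#' Per-coefficient median of the interaction (and base intensity)
#' coefficients across a list of models, with significance decided by
#' majority vote of the per-model flags — the cohort-level summary graph.
#'
#' @param models List of `mrss` models with identical layouts.
#' @param mode,adjust,filter_insignificant As in
#'   [build_interaction_graph()]; filtering is applied after aggregation
#'   using the voted flags.
#' @return An `interaction_graph`.
#' @export
median_graph <- function(models, mode = c("raw", "adjusted"),
                         filter_insignificant = FALSE,
                         adjust = c("both", "one")) {
  if (inherits(models, "mrss")) models <- list(models)
  stopifnot(length(models) >= 1)
  ref <- models[[1]]
  for (mdl in models)
    if (!identical(names(mdl$coefficients), names(ref$coefficients)))
      stop("coefficient layout mismatch across models")
  graphs <- lapply(models, build_interaction_graph, mode = mode,
                   filter_insignificant = FALSE, adjust = adjust)
  g <- graphs[[1]]
  row_stat <- function(getter, n, stat) {
    M <- matrix(vapply(graphs, getter, numeric(n)), nrow = n)
    apply(M, 1, stat)
  }
  nE <- nrow(g$edges)
  if (nE) {
    g$edges$value <- row_stat(function(gr) gr$edges$value, nE, median)
    g$edges$ci_low <- row_stat(function(gr) gr$edges$ci_low, nE, median)
    g$edges$ci_high <- row_stat(function(gr) gr$edges$ci_high, nE, median)
    g$edges$significant <- row_stat(
      function(gr) as.numeric(gr$edges$significant), nE,
      function(v) mean(v) > 0.5)
    g$edges$sign <- ifelse(g$edges$value > 0, "positive", "negative")
  }
  g$nodes$self_strength <- row_stat(function(gr) gr$nodes$self_strength,
                                    nrow(g$nodes), median)
  g$self_ranges$value <- row_stat(function(gr) gr$self_ranges$value,
                                  nrow(g$self_ranges), median)
  if (filter_insignificant) {
    g$edges <- g$edges[g$edges$significant, ]
    g$filtered <- TRUE
  }
  g
}

# node layout on a circle, deterministic in type order
graph_layout <- function(types) {
  C <- length(types)
  ang <- pi / 2 - 2 * pi * (seq_len(C) - 1) / C
  tibble(type = types,
         nx = if (C == 1) 0 else cos(ang),
         ny = if (C == 1) 0 else sin(ang))
}

#' @export
autoplot.interaction_graph <- function(object, max_linewidth = 3, ...) {
  lay <- graph_layout(object$type_set)
  nodes <- dplyr::left_join(object$nodes, lay, by = "type")
  edges <- object$edges
  if (nrow(edges)) {
    edges <- edges |>
      dplyr::left_join(lay, by = c("type_a" = "type")) |>
      dplyr::rename(xa = "nx", ya = "ny") |>
      dplyr::left_join(lay, by = c("type_b" = "type")) |>
      dplyr::rename(xb = "nx", yb = "ny")
    m <- object$n_ranges
    edges$curvature <- 0.12 * (edges$bin - (m + 1) / 2)
  }
  g <- ggplot2::ggplot()
  if (nrow(edges)) {
    # one curve layer per bin: geom_curve takes a scalar curvature
    for (b in sort(unique(edges$bin))) {
      eb <- edges[edges$bin == b, ]
      g <- g + ggplot2::geom_curve(
        data = eb,
        ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                     yend = .data$yb, colour = .data$sign,
                     linewidth = abs(.data$value)),
        curvature = eb$curvature[1], alpha = 0.8)
    }
  }
  g +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$nx, y = .data$ny,
                                     size = pmax(.data$self_strength, 0.2)),
                        colour = "grey30") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = 1.15 * .data$nx, y = 1.15 * .data$ny,
                                    label = .data$type)) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#b2182b")) +
    ggplot2::scale_linewidth(range = c(0.2, max_linewidth)) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, size = "self", linewidth = "|coef|")
}

# fixed-format numbers so rendered SVG is byte-deterministic
fmt_num <- function(x) sprintf("%.3f", x)

#' Render an interaction graph to SVG
#'
#' Writes a standalone SVG: nodes on a circle with radius proportional to
#' self-interaction strength (floored, hatched-style grey for nonpositive
#' totals), and one quadratic arc per pair and range — range order maps to
#' curvature, thickness to coefficient magnitude, blue to attraction and
#' red to repulsion. Output is deterministic given the graph and style
#' options. The drawing is generated directly (SVG is plain XML), with no
#' graphics device involved.
#'
#' @param graph An `interaction_graph`.
#' @param path Output file path.
#' @param style_options List: `size` (canvas px), `max_stroke`,
#'   `min_node_radius`, `max_node_radius`.
#' @return The path, invisibly.
#' @export
render_graph <- function(graph, path, style_options = list()) {
  so <- utils::modifyList(list(size = 600, max_stroke = 8,
                               min_node_radius = 6, max_node_radius = 30),
                          style_options)
  S <- so$size
  cx <- S / 2
  R <- 0.36 * S
  lay <- graph_layout(graph$type_set)
  px <- cx + R * lay$nx
  py <- cx - R * lay$ny
  names(px) <- names(py) <- lay$type

  strengths <- graph$nodes$self_strength
  smax <- max(strengths, 0)
  node_r <- ifelse(strengths > 0,
                   so$min_node_radius + (so$max_node_radius -
                                           so$min_node_radius) *
                     if (smax > 0) strengths / smax else 0,
                   so$min_node_radius)
  vmax <- if (nrow(graph$edges)) max(abs(graph$edges$value), 1e-9) else 1

  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'), S, S, S, S),
    sprintf('<rect width="%d" height="%d" fill="white"/>', S, S))
  if (nrow(graph$edges)) {
    e <- graph$edges[order(graph$edges$type_a, graph$edges$type_b,
                           graph$edges$bin), ]
    m <- graph$n_ranges
    for (r in seq_len(nrow(e))) {
      xa <- px[e$type_a[r]]; ya <- py[e$type_a[r]]
      xb <- px[e$type_b[r]]; yb <- py[e$type_b[r]]
      mx <- (xa + xb) / 2; my <- (ya + yb) / 2
      # perpendicular offset grows with range order
      nxv <- -(yb - ya); nyv <- xb - xa
      nl <- sqrt(nxv^2 + nyv^2)
      off <- 0.22 * nl * (e$bin[r] - (m + 1) / 2) / max(m - 1, 1)
      qx <- mx + nxv / nl * off
      qy <- my + nyv / nl * off
      col <- if (e$value[r] > 0) "#2166ac" else "#b2182b"
      sw <- 0.5 + (so$max_stroke - 0.5) * abs(e$value[r]) / vmax
      lines <- c(lines, sprintf(
        '<path d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="0.8"/>',
        fmt_num(xa), fmt_num(ya), fmt_num(qx), fmt_num(qy),
        fmt_num(xb), fmt_num(yb), col, fmt_num(sw)))
    }
  }
  for (i in seq_len(nrow(graph$nodes))) {
    tt <- graph$nodes$type[i]
    fill <- if (strengths[i] > 0) "#4d4d4d" else "#cccccc"
    dash <- if (strengths[i] > 0) "" else ' stroke-dasharray="3,2"'
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="black"%s/>',
      fmt_num(px[tt]), fmt_num(py[tt]), fmt_num(node_r[i]), fill, dash))
    lx <- cx + (R + node_r[i] + 18) * lay$nx[i]
    ly <- cx - (R + node_r[i] + 18) * lay$ny[i]
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" text-anchor="middle" font-family="sans-serif" font-size="14">%s</text>',
      fmt_num(lx), fmt_num(ly), tt))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
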