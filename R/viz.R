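# Visualisation: category bar plots, dominance-value box plots, and
# circular sociograms. Every plot function returns the plotted aggregates
# as data so results can be checked without inspecting pixels.

save_plot <- function(p, path, width = 7, height = 5) {
  if (is.null(path)) return(invisible(NULL))
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "svg", "pdf")) {
    stop_param(sprintf("unsupported image format: %s (use png, svg or pdf)", fmt))
  }
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 100)
  invisible(path)
}

#' Bar plot of animals per social category
#'
#' One bar per category (social hierarchy or social rank), height the
#' number of animals in it.
#'
#' @param t a `dominance_table` (non-empty) with the requested category
#'   column.
#' @param grouping `"social_hierarchy"` (default) or `"social_rank"`.
#' @param path optional output image path (`.png`, `.svg` or `.pdf`).
#' @return invisibly, a list with `counts` (named integer vector, category
#'   order as in the table's ascending-dominance layout) and `plot` (the
#'   ggplot object).
#' @export
plot_dominance_bar <- function(t, grouping = c("social_hierarchy", "social_rank"),
                               path = NULL) {
  grouping <- match.arg(grouping)
  if (nrow(t) == 0L) stop_param("dominance table is empty")
  if (!grouping %in% names(t)) {
    stop_schema(sprintf("dominance table has no column %s", grouping))
  }
  lv <- unique(t[[grouping]])  # table is sorted by ascending dominance value
  cat_f <- factor(t[[grouping]], levels = lv)
  counts <- table(cat_f)
  df <- data.frame(category = factor(names(counts), levels = lv),
                   n = as.integer(counts))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = gsub("_", " ", grouping), y = "number of animals") +
    ggplot2::theme_minimal()
  save_plot(p, path)
  invisible(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 plot = p))
}

#' Box plot of dominance values per social category
#'
#' @inheritParams plot_dominance_bar
#' @param values column to summarise, default `"dominance_value"`.
#' @return invisibly, a list with `stats` (a data frame of per-category
#'   min, q1, median, q3, max, mean, sd, n) and `plot`.
#' @export
plot_dominance_box <- function(t, values = "dominance_value",
                               grouping = c("social_hierarchy", "social_rank"),
                               path = NULL) {
  grouping <- match.arg(grouping)
  if (nrow(t) == 0L) stop_param("dominance table is empty")
  for (col in c(values, grouping)) {
    if (!col %in% names(t)) stop_schema(sprintf("dominance table has no column %s", col))
  }
  lv <- unique(t[[grouping]])
  sp <- split(as.numeric(t[[values]]), factor(t[[grouping]], levels = lv))
  st <- do.call(rbind, lapply(names(sp), function(g) {
    v <- sp[[g]]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(category = g, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  df <- data.frame(category = factor(t[[grouping]], levels = lv),
                   value = as.numeric(t[[values]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = gsub("_", " ", grouping), y = gsub("_", " ", values)) +
    ggplot2::theme_minimal()
  save_plot(p, path)
  invisible(list(stats = st, plot = p))
}

#' Circular sociogram of the group's interactions
#'
#' Animals are laid out on a circle in canonical label order; a directed
#' edge i -> j is drawn for every `X[i, j] > 0`, with width proportional
#' to the count (normalised to the largest count). `direction = "actor"`
#' draws arrows from actor to reactor; `direction = "reactor"` transposes
#' the matrix first, so arrows point from the displaced animal to its
#' displacer.
#'
#' @param m a non-empty `socio_matrix`.
#' @param direction `"actor"` (default) or `"reactor"`.
#' @param path optional output image path (`.png`, `.svg` or `.pdf`).
#' @param max_width widest edge in plot units.
#' @return invisibly, a list with `edges` (data frame `from`, `to`,
#'   `weight`, `width`) and `graph` (the igraph object).
#' @export
plot_sociogram <- function(m, direction = c("actor", "reactor"), path = NULL,
                           max_width = 6) {
  direction <- match.arg(direction)
  if (nrow(m) == 0L) stop_param("sociomatrix is empty")
  X <- unclass(m)
  if (direction == "reactor") X <- t(X)
  idx <- which(X > 0, arr.ind = TRUE)
  edges <- data.frame(from = rownames(X)[idx[, 1]],
                      to = colnames(X)[idx[, 2]],
                      weight = X[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) {
    warning("all-zero sociomatrix: sociogram has no edges")
    edges$width <- numeric(0)
  } else {
    edges$width <- max_width * edges$weight / max(edges$weight)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = rownames(X)))
  if (!is.null(path)) {
    fmt <- tolower(tools::file_ext(path))
    if (!fmt %in% c("png", "svg", "pdf")) {
      stop_param(sprintf("unsupported image format: %s (use png, svg or pdf)", fmt))
    }
    switch(fmt,
           png = grDevices::png(path, width = 700, height = 700, res = 100),
           svg = grDevices::svg(path, width = 7, height = 7),
           pdf = grDevices::pdf(path, width = 7, height = 7))
    on.exit(grDevices::dev.off(), add = TRUE)
    igraph::plot.igraph(g, layout = igraph::layout_in_circle(g),
                        edge.width = if (nrow(edges) > 0) edges$width else 1,
                        edge.arrow.size = 0.4, vertex.size = 14,
                        vertex.color = "lightsteelblue",
                        vertex.label.cex = 0.8)
  }
  invisible(list(edges = edges, graph = g))
}
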