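#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname rna_fold
#' @param x an `rna_fold` object.
#' @param ... unused.
#' @export
tidy.rna_fold <- function(x, ...) {
  if (is.null(x$pairs) || nrow(x$pairs) == 0L) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          base_i = character(0), base_j = character(0),
                          pair_score = integer(0)))
  }
  tibble::tibble(
    i = x$pairs$i, j = x$pairs$j,
    base_i = substring(x$seq$residues, x$pairs$i, x$pairs$i),
    base_j = substring(x$seq$residues, x$pairs$j, x$pairs$j),
    pair_score = vapply(seq_len(nrow(x$pairs)), function(k) {
      as.integer(pair_score(x$scheme, x$seq, x$pairs$i[k], x$pairs$j[k]))
    }, integer(1)))
}

#' @rdname rna_fold
#' @export
glance.rna_fold <- function(x, ...) {
  tibble::tibble(id = x$seq$id, n = x$seq$n, score = as.integer(x$score),
                 n_pairs = if (is.null(x$pairs)) NA_integer_ else nrow(x$pairs),
                 algorithm = x$algorithm,
                 q = if (is.null(x$q)) NA_integer_ else x$q,
                 d = x$scheme$d, C = x$scheme$C)
}

#' @rdname fold_column
#' @param x a `score_matrix` object.
#' @param ... unused.
#' @export
tidy.score_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$S, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(i = idx[, "row"], j = idx[, "col"], score = x$S[idx])
}

#' @rdname fold_column
#' @export
glance.score_matrix <- function(x, ...) {
  tibble::tibble(n = x$n, score = as.integer(optimal_score(x)),
                 algorithm = x$algorithm,
                 q = if (is.null(x$q)) NA_integer_ else x$q,
                 d = x$scheme$d, C = x$scheme$C)
}

#' Arc diagram of a folded structure
#'
#' Sites on a horizontal axis; each base pair drawn as an arc. Height is
#' proportional to pairing distance, so nesting is visible directly.
#'
#' @param object an `rna_fold` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rna_fold <- function(object, ...) {
  n <- object$seq$n
  base_df <- tibble::tibble(x = seq_len(n),
                            base = strsplit(object$seq$residues, "")[[1L]])
  p <- ggplot2::ggplot(base_df, ggplot2::aes(x = .data$x, y = 0))
  if (!is.null(object$pairs) && nrow(object$pairs) > 0L) {
    arcs <- purrr::map_dfr(seq_len(nrow(object$pairs)), function(k) {
      i <- object$pairs$i[k]; j <- object$pairs$j[k]
      t <- seq(0, pi, length.out = 50)
      tibble::tibble(pair = k,
                     x = (i + j) / 2 + (j - i) / 2 * cos(t),
                     y = (j - i) / 2 * sin(t))
    })
    p <- p + ggplot2::geom_path(data = arcs,
                                ggplot2::aes(x = .data$x, y = .data$y, group = .data$pair),
                                colour = "steelblue")
  }
  if (n <= 80) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 0.4)
  }
  p + ggplot2::labs(x = "site", y = NULL,
                    title = sprintf("%s  (score %d)", object$seq$id, object$score)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Heatmap of a folding score matrix
#'
#' @param object a `score_matrix` object.
#' @param ... unused.
#' @return A ggplot of the upper triangle of S.
#' @export
autoplot.score_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("S matrix (%s solver)", object$algorithm),
                  x = "j", y = "i") +
    ggplot2::theme_minimal()
}

#' Benchmark timing plot
#'
#' @param bench a tibble from [run_bench()].
#' @return A ggplot of the speedup ratio against n.
#' @export
plot_bench <- function(bench) {
  ggplot2::ggplot(bench, ggplot2::aes(x = .data$size, y = .data$ratio)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "sequence length n", y = "cubic / four-russians time",
                  title = "Four-Russians speedup ratio (hardware-dependent)") +
    ggplot2::theme_minimal()
}
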