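# broom-style accessors and ggplot2 methods for scan results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a composition scan
#'
#' One row per (composition, pairing) record with list columns flattened to
#' labels.
#'
#' @param x a `ddg_scan` from [scan_compositions()].
#' @param ... unused.
#' @return a plain tibble.
#' @export
tidy.ddg_scan <- function(x, ...) {
  out <- as_tibble(x)
  out$left <- vapply(out$left, paste, character(1), collapse = "+")
  out$right <- vapply(out$right, paste, character(1), collapse = "+")
  out$flags <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.ddg_scan
#' @export
glance.ddg_scan <- function(x, ...) {
  sp <- attr(x, "spec")
  tibble(n_records = nrow(x),
         n_compositions = length(unique(x$composition)),
         assembly_kind = attr(x, "assembly_kind") %||% NA_character_,
         mutation = if (!is.null(sp)) sprintf("%s:%d:%s>%s", sp$chain, sp$resno,
                                              sp$wt, sp$mut) else NA_character_,
         max_mutations = max(x$n_mut))
}

#' Tidy pooled scan statistics into long form
#'
#' @param x a `ddg_pooled` from [pool_ddg()].
#' @param ... unused.
#' @return tibble with n_mut, n, quantity ("binding"/"folding"), component
#'   ("app"/"coulomb"/"solv"), mean, sd.
#' @export
tidy.ddg_pooled <- function(x, ...) {
  long <- as_tibble(x) %>%
    tidyr::pivot_longer(-dplyr::all_of(c("n_mut", "n")),
                        names_to = c("quantity", "component", "stat"),
                        names_pattern = "ddg_([bf])_(app|coulomb|solv)_(mean|sd)",
                        values_to = "value") %>%
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  long$quantity <- c(b = "binding", f = "folding")[long$quantity]
  long
}

#' @rdname tidy.ddg_pooled
#' @export
glance.ddg_pooled <- function(x, ...) {
  tibble(n_groups = nrow(x), n_records = sum(x$n),
         monotone_binding = !is.unsorted(x$ddg_b_app_mean),
         monotone_folding = !is.unsorted(x$ddg_f_app_mean))
}

#' @export
tidy.oligovar_run <- function(x, ...) {
  purrr::map_dfr(names(x$pooled), function(m) {
    out <- tidy(x$pooled[[m]])
    out$mode <- m
    out
  })
}

#' @export
glance.oligovar_run <- function(x, ...) {
  tibble(config_hash = x$hash,
         modes = paste(names(x$pooled), collapse = "+"),
         n_records = sum(vapply(x$records, nrow, integer(1))),
         deleted_waters = x$prep_report$deleted_waters,
         minimization_rmsd = x$prep_report$final_heavy_atom_rmsd)
}

#' Plot pooled ddG against mutation count
#'
#' Mean with +/- SD error bars for the apparent binding and folding ddG,
#' the qualitative pattern of a Table-3-style report.
#'
#' @param object a `ddg_pooled`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ddg_pooled <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$component == "app")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_mut, y = .data$mean,
                                  color = .data$quantity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::labs(x = "mutated protomers", y = "apparent ddG (kcal/mol)",
                  color = NULL) +
    ggplot2::scale_x_continuous(breaks = unique(d$n_mut)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-record ddG values by composition
#' @param object a `ddg_scan`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ddg_scan <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(dplyr::any_of(c("ddg_b_app", "ddg_f_app")),
                        names_to = "quantity", values_to = "value") %>%
    filter(!is.na(.data$value))
  d$quantity <- c(ddg_b_app = "binding", ddg_f_app = "folding")[d$quantity]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_mut), y = .data$value,
                                  color = .data$quantity)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "mutated protomers", y = "apparent ddG (kcal/mol)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot aggregation scores along the sequence
#' @param object tibble from [aggregation_rank()].
#' @param top_n label the top-ranked residues.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_aggregation <- function(object, top_n = 3, ...) {
  lab <- object %>% filter(!is.na(.data$rank), .data$rank <= top_n)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$resno, y = .data$score)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$buried)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = paste0(.data$resname, .data$resno)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "grey70"),
                               name = "buried") +
    ggplot2::labs(x = "residue", y = "aggregation score") +
    ggplot2::theme_minimal()
}

#' Plot a mid-plane slice of a grid potential
#' @param object a `grid_potential`.
#' @param axis slicing axis ("z" default).
#' @param bounds color bounds in kT/e.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grid_potential <- function(object, axis = "z", bounds = c(-10, 10), ...) {
  d <- object$dims
  k <- ceiling(d[3] / 2)
  sl <- object$values[, , k]
  df <- expand.grid(x = object$origin[1] + (0:(d[1] - 1)) * object$spacing,
                    y = object$origin[2] + (0:(d[2] - 1)) * object$spacing)
  df$phi <- pmin(pmax(as.numeric(sl), bounds[1]), bounds[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  name = "kT/e") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)") +
    ggplot2::theme_minimal()
}
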