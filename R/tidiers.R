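# broom-style tidiers

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a discordance decomposition
#'
#' @param x A `discord_decomposition`.
#' @param ... Unused.
#' @return One row per factor: `term`, `share`, `percent`, `first`,
#'   `last`.
#' @method tidy discord_decomposition
#' @export
tidy.discord_decomposition <- function(x, ...) {
  tibble::tibble(
    term = names(x$shares),
    share = as.numeric(x$shares),
    percent = as.numeric(x$percent),
    first = as.numeric(x$first),
    last = as.numeric(x$last)
  )
}

#' @rdname tidy.discord_decomposition
#' @method glance discord_decomposition
#' @export
glance.discord_decomposition <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n_nodes = x$n_nodes,
                 n_dropped_rows = x$n_dropped_rows)
}

#' Tidy a genealogy scan
#'
#' @param x A `genealogy_scan`.
#' @param ... Unused.
#' @return `tidy()`: the per-window classification tibble; `glance()`:
#'   the one-row summary (class fractions, ILS%, tau).
#' @method tidy genealogy_scan
#' @export
tidy.genealogy_scan <- function(x, ...) x$windows

#' @rdname tidy.genealogy_scan
#' @method glance genealogy_scan
#' @export
glance.genealogy_scan <- function(x, ...) x$summary
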