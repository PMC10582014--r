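# broom-style tidiers and small print methods for the result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for pednar results
#'
#' `tidy()` returns the per-unit table (per MAG, per category); `glance()`
#' returns a one-row summary.
#'
#' @param x A pednar result object.
#' @param ... Unused.
#' @return A tibble.
#' @name pednar-tidiers
NULL

#' @rdname pednar-tidiers
#' @method tidy pedna_mechanism
#' @export
tidy.pedna_mechanism <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pedna_mechanism")
  out
}

#' @rdname pednar-tidiers
#' @method glance pedna_mechanism
#' @export
glance.pedna_mechanism <- function(x, ...) {
  tibble(n_mags = nrow(x),
         n_ev = sum(x$label == "EV_producer"),
         n_gta = sum(x$label == "GTA_producer"),
         n_transducer = sum(x$label == "transducer"),
         n_unclear = sum(x$label == "unclear"))
}

#' @rdname pednar-tidiers
#' @method glance pedna_split
#' @export
glance.pedna_split <- function(x, ...) {
  tibble(n_pairs_viral = x$n_pairs_viral,
         n_pairs_nonviral = x$n_pairs_nonviral,
         n_pairs_unmapped = x$n_pairs_unmapped,
         nv_ratio = x$nv_ratio,
         nv_percent = 100 * x$nv_ratio)
}

#' @rdname pednar-tidiers
#' @method glance pedna_ssu
#' @export
glance.pedna_ssu <- function(x, ...) {
  tibble(n_pairs_total = x$n_pairs_total, n_pairs_ssu = x$n_pairs_ssu,
         rate_percent = x$rate_percent)
}

#' @rdname pednar-tidiers
#' @method tidy pedna_cog_profile
#' @export
tidy.pedna_cog_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pedna_cog_profile")
  out
}

#' @export
print.pedna_split <- function(x, ...) {
  cat(sprintf(
    "peDNA split report [%s]: %d viral / %d non-viral / %d unmapped pairs; nv ratio %.3f\n",
    x$sample_id, x$n_pairs_viral, x$n_pairs_nonviral, x$n_pairs_unmapped,
    x$nv_ratio))
  invisible(x)
}

#' @export
print.pedna_ssu <- function(x, ...) {
  cat(sprintf(
    "SSU screen [%s]: %d / %d pairs (%.4f%%); metagenome mean %.3f%% shown for context only\n",
    x$sample_id, x$n_pairs_ssu, x$n_pairs_total, x$rate_percent,
    x$ref_metagenome_mean_percent))
  invisible(x)
}
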