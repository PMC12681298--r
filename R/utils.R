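#' @keywords internal
"_PACKAGE"

abort <- function(msg, class) {
  stop(structure(class = c(class, "tofrecon_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg, class = "tofrecon_invalid") {
  if (!isTRUE(cond)) abort(msg, class)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a global seed and a component tag
#'
#' Every stochastic stage of the pipeline (phantom generation, phase and coil
#' simulation, per-epoch mask draws, weight initialisation) receives its own
#' seed derived deterministically from the global run seed plus a stable text
#' tag and an optional index, so that "a fresh mask each time a dataset is
#' loaded" is reproducible across machines and sessions.
#'
#' @param seed integer global seed.
#' @param tag character component tag, e.g. `"mask"`.
#' @param index optional integer (epoch, dataset id, ...).
#' @return integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- (as.double(seed) %% 2147483647) + 1
  codes <- c(utf8ToInt(as.character(tag)), 31L, index + 1L)
  for (v in codes) {
    h <- (h * 48271 + as.double(v) * 16807) %% 2147483647
  }
  as.integer(h %% 2147483646)
}

# round half away from zero (base R round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# relative L2 error
rel_err <- function(a, b) {
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) return(sqrt(sum(Mod(a)^2)))
  sqrt(sum(Mod(a - b)^2)) / nb
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
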