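#' Controller specifications for the closed-loop simulator
#'
#' Three control laws are available: the baseline LQ-integral regulator
#' (`controller_lqir`), the fixed-gain hybrid sliding-mode law
#' (`controller_lq_smc`, `u = u_lq - Mo * limiter(s)`) and the self-adaptive
#' hybrid law (`controller_lq_asmc`, `u = u_lq - M(err) * tanh(s)` with the
#' hyperbolic-secant gain schedule). The default gain vector is the
#' published tuned set ([tuned_gain_published()]); pass `K` explicitly to
#' use e.g. a freshly synthesized [lqir_design()] gain.
#'
#' @param K state-feedback gain 4-vector.
#' @param sliding a [sliding_config()]; its `adaptive`/`mode` fields are
#'   overridden to match the chosen law.
#' @return Object of class `controller_spec`.
#' @export
controller_lqir <- function(K = tuned_gain_published()) {
  structure(list(type = "lqir", K = K, sliding = NULL),
            class = "controller_spec")
}

#' @rdname controller_lqir
#' @param mode reaching-law limiter for the fixed-gain law (`"tanh"`
#'   default, or `"sgn"`).
#' @export
controller_lq_smc <- function(K = tuned_gain_published(),
                              sliding = sliding_config(),
                              mode = c("tanh", "sgn")) {
  sliding$mode <- match.arg(mode)
  sliding$adaptive <- FALSE
  structure(list(type = "lq-smc", K = K, sliding = sliding),
            class = "controller_spec")
}

#' @rdname controller_lqir
#' @export
controller_lq_asmc <- function(K = tuned_gain_published(),
                               sliding = sliding_config()) {
  sliding$mode <- "tanh"
  sliding$adaptive <- TRUE
  structure(list(type = "lq-asmc", K = K, sliding = sliding),
            class = "controller_spec")
}

#' Controller lookup by name
#' @param name `"lqir"`, `"lq-smc"` or `"lq-asmc"`.
#' @param ... passed to the matching constructor.
#' @return A `controller_spec`.
#' @export
controller_by_name <- function(name, ...) {
  switch(tolower(name),
         "lqir" = controller_lqir(...),
         "lq-smc" = controller_lq_smc(...),
         "lq-asmc" = controller_lq_asmc(...),
         stop("unknown controller '", name,
              "'; valid: lqir, lq-smc, lq-asmc", call. = FALSE))
}

#' @export
print.controller_spec <- function(x, ...) {
  cat(sprintf("Controller '%s', K = (%s)\n", x$type,
              paste(signif(x$K, 4), collapse = ", ")))
  if (!is.null(x$sliding)) print(x$sliding)
  invisible(x)
}
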