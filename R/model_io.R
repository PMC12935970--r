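# Declarative membrane model files.
#
# Rate expressions are strings in a deliberately small arithmetic grammar:
# the variable v, numeric literals, + - * / ^, parentheses, and the
# functions exp, log, log10, sqrt, tanh, pow(x, y) and expm1_div(x)
# (= x / (exp(x) - 1), evaluated stably near 0, the standard guard for
# alpha-rate expressions with removable singularities). Anything else is
# rejected at load time, and every expression is validated on a voltage
# grid before use.

RATE_FUNS <- c("exp", "log", "log10", "sqrt", "tanh", "pow", "expm1_div")
RATE_OPS <- c("+", "-", "*", "/", "^", "(")

expm1_div <- function(x) {
  out <- x / expm1(x)
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  out
}

rate_env <- local({
  e <- new.env(parent = baseenv())
  e$pow <- function(x, y) x^y
  e$expm1_div <- expm1_div
  e
})

check_rate_ast <- function(expr, src) {
  if (is.numeric(expr) || is.integer(expr)) return(invisible(TRUE))
  if (is.symbol(expr)) {
    if (!identical(as.character(expr), "v")) {
      stop(sprintf("rate expression '%s': unknown symbol '%s' (only 'v' is allowed)",
                   src, as.character(expr)), call. = FALSE)
    }
    return(invisible(TRUE))
  }
  if (is.call(expr)) {
    fn <- as.character(expr[[1]])
    if (!fn %in% c(RATE_FUNS, RATE_OPS)) {
      stop(sprintf("rate expression '%s': function or operator '%s' is not in the model grammar",
                   src, fn), call. = FALSE)
    }
    for (k in seq_along(expr)[-1]) check_rate_ast(expr[[k]], src)
    return(invisible(TRUE))
  }
  stop(sprintf("rate expression '%s': unsupported construct", src), call. = FALSE)
}

# Compile a rate-expression string into a vectorized function of v.
parse_rate_expr <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  expr <- tryCatch(str2lang(s), error = function(e) {
    stop(sprintf("unparsable rate expression '%s': %s", s, conditionMessage(e)),
         call. = FALSE)
  })
  check_rate_ast(expr, s)
  function(v) eval(expr, list(v = v), rate_env)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a membrane model from a declarative YAML file
#'
#' The schema (version 1) mirrors the structure of published
#' compartmental-model channel tables: a list of channels, each with a
#' reversal potential, a per-region conductance-density table and gate
#' kinetics given as expression strings; plus a per-region capacitance
#' table. Expressions are validated on a -120..60 mV grid at load time
#' (tau > 0, steady states in [0, 1]). Bundled examples: `hh.yaml`,
#' `passive.yaml` under `system.file("models", package = "emisim")`.
#'
#' @param path Path to the model file.
#' @return A [membrane_model()].
#' @export
load_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  check_keys(spec, c("schema_version", "name", "capacitance_uF_per_cm2",
                     "spontaneous", "channels"), basename(path))
  if (!identical(as.integer(spec$schema_version), 1L)) {
    stop("unsupported model schema_version (expected 1)")
  }
  channels <- lapply(spec$channels, function(ch) {
    check_keys(ch, c("name", "reversal_mV", "conductance_mS_per_cm2", "gates"),
               sprintf("channel '%s'", ch$name %||% "?"))
    gates <- lapply(ch$gates %||% list(), function(g) {
      check_keys(g, c("name", "exponent", "alpha", "beta", "inf", "tau"),
                 sprintf("gate '%s'", g$name %||% "?"))
      gate_spec(g$name, exponent = g$exponent %||% 1,
                alpha = g$alpha, beta = g$beta, inf = g$inf, tau = g$tau)
    })
    channel_spec(ch$name, ch$reversal_mV, unlist(ch$conductance_mS_per_cm2),
                 gates)
  })
  membrane_model(channels,
                 cm_uF_per_cm2 = unlist(spec$capacitance_uF_per_cm2),
                 name = spec$name %||% "model",
                 spontaneous = isTRUE(spec$spontaneous))
}

#' Serialize a membrane model to the YAML schema
#'
#' Inverse of [load_model_spec()] for models whose gate kinetics were built
#' from expression strings (all bundled models are).
#'
#' @param model A [membrane_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_spec <- function(model, path) {
  chans <- lapply(model$channels, function(ch) {
    out <- list(name = ch$name, reversal_mV = ch$reversal_mV,
                conductance_mS_per_cm2 = as.list(ch$g_mS_per_cm2))
    if (length(ch$gates)) {
      out$gates <- lapply(ch$gates, function(g) {
        gl <- list(name = g$name, exponent = g$exponent)
        for (f in c("alpha", "beta", "inf", "tau")) {
          if (!is.null(g[[f]])) gl[[f]] <- g[[f]]
        }
        gl
      })
    }
    out
  })
  yaml::write_yaml(list(schema_version = 1L, name = model$name,
                        spontaneous = isTRUE(model$spontaneous),
                        capacitance_uF_per_cm2 = as.list(model$cm_uF_per_cm2),
                        channels = chans), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a model reference: a bundled name ("hh", "passive") or a file path.
resolve_model <- function(ref) {
  if (inherits(ref, "membrane_model")) return(ref)
  stopifnot(is.character(ref), length(ref) == 1L)
  if (ref == "hh") return(hh_model())
  if (ref == "passive") return(passive_model())
  if (ref == "hh-ais") return(fixture_ais_model())
  if (ref == "hh-pacemaker") return(fixture_pacemaker_model())
  if (file.exists(ref)) return(load_model_spec(ref))
  bundled <- system.file("models", paste0(ref, ".yaml"), package = "emisim")
  if (nzchar(bundled)) return(load_model_spec(bundled))
  stop("unknown membrane model reference: ", ref)
}
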