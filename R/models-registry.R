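# Model registry: each entry bundles a simulator, generator, exact (or
# numerical) likelihood where available, parameter names and default
# bounds, so the engine, the fitting code and the CLI can refer to models
# by name.

.model_registry <- new.env(parent = emptyenv())

#' Register or look up a generative model
#'
#' A model entry is a list with fields:
#' `simulate(stimulus, params)` (one response), optional
#' `simulate_n(stimulus, params, n)` (vectorized), optional
#' `generate(params, cfg, seed)` returning [trial_data()], optional
#' `exact_loglik(data, params)` and `trial_probs(data, params)`,
#' `param_names`, `lower`/`upper` default bounds, `default_task()` and
#' `response_space_size`.
#'
#' Built-in models: `"orientation"`, `"changeloc"`, and a `"bernoulli"`
#' toy model (single parameter `p`, stimulus ignored, response 1 with
#' probability `p`) used for testing and as a minimal plug-in example.
#'
#' @param name model name.
#' @param model model entry list (see Details).
#' @return `get_model()` returns the entry; `list_models()` the
#'   registered names.
#' @export
register_model <- function(name, model) {
  stopifnot(is.character(name), length(name) == 1L, is.list(model))
  required <- c("simulate", "param_names", "lower", "upper")
  missing <- setdiff(required, names(model))
  if (length(missing)) {
    stop("model entry lacks fields: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  assign(name, model, envir = .model_registry)
  invisible(name)
}

#' @rdname register_model
#' @export
get_model <- function(name) {
  if (!exists(name, envir = .model_registry, inherits = FALSE)) {
    stop("unknown model '", name, "'; registered: ",
      paste(list_models(), collapse = ", "),
      call. = FALSE
    )
  }
  get(name, envir = .model_registry, inherits = FALSE)
}

#' @rdname register_model
#' @export
list_models <- function() {
  sort(ls(envir = .model_registry))
}

#' Simulator function for a registry entry
#'
#' Returns the model's scalar simulator with its vectorized variants
#' (`simulate_n`, `simulate_vec`) attached as attributes, ready to pass
#' to [ibs_loglik()] or [fixed_loglik()].
#'
#' @param model a model entry from [get_model()].
#' @return the simulator function.
#' @export
model_simulator <- function(model) {
  sim <- model$simulate
  if (!is.null(model$simulate_n)) attr(sim, "simulate_n") <- model$simulate_n
  if (!is.null(model$simulate_vec)) {
    attr(sim, "simulate_vec") <- model$simulate_vec
  }
  sim
}

register_builtin_models <- function() {
  register_model("orientation", list(
    simulate = orientation_simulate,
    simulate_n = orientation_simulate_n,
    simulate_vec = orientation_simulate_vec,
    generate = orientation_generate_dataset,
    exact_loglik = orientation_exact_loglik,
    trial_probs = orientation_trial_probs,
    param_names = c("eta", "mu", "gamma"),
    # default plausible ranges: sigma 0.1..10 degrees, bias within 2
    # degrees, lapse 0.005..0.5
    lower = c(eta = log(0.1), mu = -2, gamma = 0.005),
    upper = c(eta = log(10), mu = 2, gamma = 0.5),
    default_task = orientation_task,
    response_space_size = 2L
  ))
  register_model("changeloc", list(
    simulate = changeloc_simulate,
    simulate_vec = changeloc_simulate_vec,
    generate = changeloc_generate_dataset,
    exact_loglik = changeloc_exact_loglik,
    trial_probs = changeloc_trial_probs,
    param_names = c("eta", "gamma"),
    # sigma 1..60 degrees
    lower = c(eta = log(1), gamma = 0.005),
    upper = c(eta = log(60), gamma = 0.5),
    default_task = changeloc_task,
    response_space_size = 6L
  ))
  register_model("bernoulli", list(
    simulate = function(stimulus, params) {
      as.integer(runif(1) < params[["p"]])
    },
    simulate_n = function(stimulus, params, n) {
      as.integer(runif(n) < params[["p"]])
    },
    simulate_vec = function(stimuli, params) {
      as.integer(runif(length(stimuli)) < params[["p"]])
    },
    generate = function(params, cfg = list(n_trials = 100L), seed = 1L) {
      old <- preserve_rng()
      on.exit(restore_rng(old), add = TRUE)
      seed_rng(seed)
      r <- as.integer(runif(cfg$n_trials) < params[["p"]])
      trial_data(rep(0, cfg$n_trials), r)
    },
    exact_loglik = function(data, params) {
      r <- vapply(data$responses, function(x) x[[1]], numeric(1))
      sum(log(ifelse(r == 1, params[["p"]], 1 - params[["p"]])))
    },
    trial_probs = function(data, params) {
      r <- vapply(data$responses, function(x) x[[1]], numeric(1))
      ifelse(r == 1, params[["p"]], 1 - params[["p"]])
    },
    param_names = "p",
    lower = c(p = 1e-6),
    upper = c(p = 1),
    default_task = function() list(n_trials = 100L),
    response_space_size = 2L
  ))
}

.onLoad <- function(libname, pkgname) {
  register_builtin_models()
}
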