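#' Configuration for a comparison run
#'
#' Bundles everything \code{\link{run_comparison}} needs: the nonlinear
#' model, the gradient, the linearization targets to lay alongside it, the
#' requested bifurcation detections and the output paths.
#'
#' @param model nonlinear tag (LVV, RM or RMS; LV has no gradient
#'   structure).
#' @param parameter,lo,hi,n_points forwarded to
#'   \code{\link{gradient_spec}}.
#' @param linearizations character vector of targets among
#'   \code{c("LV", "LVV", "RM")}, each strictly simpler than \code{model}.
#' @param events which detections to run, subset of
#'   \code{c("transcritical", "hopf", "fold", "global")}.
#' @param out_csv,out_events output paths (CSV gradient table, JSON event
#'   list).
#' @param neutral_tol,seed numerical tolerance for regime classification
#'   and RNG seed (recorded for reproducibility; the computations here are
#'   deterministic).
#' @param params model parameters (defaults to \code{\link{cr_params}()}).
#' @return object of class \code{cr_run_config}.
#' @export
run_config <- function(model, parameter = c("K", "F"), lo = NULL, hi = NULL,
                       n_points = 1000L,
                       linearizations = c("LV"),
                       events = c("transcritical", "hopf", "fold", "global"),
                       out_csv = "gradient_table.csv",
                       out_events = "events.json",
                       neutral_tol = 1e-9, seed = 1L,
                       params = cr_params()) {
  check_variant(model)
  if (is_linearized(model) || model == "LV")
    stop("model must be LVV, RM or RMS")
  grad <- gradient_spec(match.arg(parameter), lo, hi, n_points)
  order_ <- c(LV = 1, LVV = 2, RM = 3, RMS = 4)
  bad <- linearizations[order_[linearizations] >= order_[[model]] |
                          !(linearizations %in% c("LV", "LVV", "RM"))]
  if (length(bad) || anyNA(order_[linearizations]))
    stop("invalid linearization target(s): ",
         paste(unique(c(bad, linearizations[is.na(order_[linearizations])])),
               collapse = ", "))
  events <- match.arg(events, several.ok = TRUE)
  structure(list(model = model, grad = grad,
                 linearizations = linearizations, events = events,
                 out_csv = out_csv, out_events = out_events,
                 neutral_tol = neutral_tol, seed = as.integer(seed),
                 params = params),
            class = "cr_run_config")
}

#' Read a run configuration from a key=value file
#'
#' Keys mirror the arguments of \code{\link{run_config}}
#' (comma-separated lists for \code{linearizations} and \code{events};
#' model parameter keys such as \code{r}, \code{K}, ... override the
#' defaults).
#'
#' @param path configuration file.
#' @return a \code{cr_run_config}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  getv <- function(k, default = NULL) if (k %in% keys)
    vals[[match(k, keys)]] else default
  pkeys <- intersect(keys, names(formals(cr_params)))
  params <- do.call(cr_params, as.list(setNames(
    as.numeric(vals[match(pkeys, keys)]), pkeys)))
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  run_config(model = getv("model", stop("config needs 'model'")),
             parameter = getv("parameter", "K"),
             lo = num(getv("lo")), hi = num(getv("hi")),
             n_points = as.integer(getv("n_points", "1000")),
             linearizations = strsplit(getv("linearizations", "LV"),
                                       ",")[[1L]],
             events = strsplit(
               getv("events", "transcritical,hopf,fold,global"), ",")[[1L]],
             out_csv = getv("out_csv", "gradient_table.csv"),
             out_events = getv("out_events", "events.json"),
             neutral_tol = as.numeric(getv("neutral_tol", "1e-9")),
             seed = as.integer(getv("seed", "1")),
             params = params)
}

#' Run a nonlinear-vs-linearized comparison along a gradient
#'
#' Sweeps the nonlinear model and each requested linearized counterpart
#' over the same gradient, assembles one flat table (a \code{variant}
#' column distinguishes the systems -- the side-by-side Re(lambda) content
#' of the reference figures), runs the requested bifurcation detections on
#' the nonlinear model, and writes both outputs.  Re-running the same
#' configuration reproduces the files byte for byte (all solvers are
#' deterministic).
#'
#' @param config a \code{\link{run_config}}.
#' @return invisibly, \code{list(table, events)}.
#' @export
run_comparison <- function(config) {
  if (!inherits(config, "cr_run_config"))
    stop("config must be a run_config()")
  set.seed(config$seed)
  variants <- c(config$model,
                paste(config$model, config$linearizations, sep = "_"))
  tabs <- lapply(variants, function(v) {
    tb <- sweep_gradient(v, config$params, config$grad,
                         neutral_tol = config$neutral_tol)
    cbind(variant = v, as.data.frame(tb))
  })
  table <- do.call(rbind, tabs)
  events <- list()
  grab <- function(expr) tryCatch(expr, error = function(e) {
    message("detection skipped: ", conditionMessage(e))
    NULL
  })
  if ("transcritical" %in% config$events)
    for (v in variants) {
      ev <- grab(detect_transcritical(v, config$params, config$grad))
      if (!is.null(ev)) { ev$variant <- v; events <- c(events, list(ev)) }
    }
  if ("hopf" %in% config$events) {
    ev <- grab(detect_hopf(config$model, config$params, config$grad))
    if (!is.null(ev)) { ev$variant <- config$model
      events <- c(events, list(ev)) }
  }
  if ("fold" %in% config$events) {
    evs <- grab(detect_fold(config$model, config$params, config$grad))
    for (ev in evs) { ev$variant <- config$model
      events <- c(events, list(ev)) }
  }
  if ("global" %in% config$events && config$model == "RMS" &&
      config$grad$parameter == "F") {
    evs <- grab(detect_global(config$params, config$grad))
    for (ev in evs) { ev$variant <- "RMS"; events <- c(events, list(ev)) }
  }
  for (ev in events)
    message(sprintf("detected %s for %s at %s = %.6g (tol %.2g)",
                    ev$kind, ev$variant, config$grad$parameter,
                    ev$param_value, ev$refinement_tol))
  write.csv(table, config$out_csv, row.names = FALSE, quote = FALSE)
  obj <- lapply(events, function(ev)
    list(variant = ev$variant, kind = ev$kind,
         param_value = ev$param_value, branch_id = ev$branch_id,
         refinement_tol = ev$refinement_tol))
  jsonlite::write_json(obj, config$out_events, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(table = table, events = events))
}
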