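#' Read and validate a run configuration
#'
#' Configurations are flat YAML key-value files whose keys mirror the
#' command-line flags of the bundled `surv2stage` script. Unknown keys and
#' out-of-range values raise an error naming the offending key; defaults
#' are filled for everything omitted.
#'
#' Recognised keys: `alpha`, `power`, `tc`, `s0`, `s1`, `hr`, `shape`,
#' `shape0`, `shape1`, `accrual`, `c1_lo`, `c1_hi`, `c1_step`, `n_start`,
#' `n_max`, `stop_factor`, `calibrate`, `reps`, `seed`, `p0`, `p1`,
#' `nmax`, `out`, `format`.
#'
#' @param path Path to a YAML file.
#' @return A named list of class `"surv2stage_config"` with defaults
#'   applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config A configuration list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[order(names(config))], path)
  invisible(path)
}

config_defaults <- function() {
  list(alpha = 0.05, power = 0.80, tc = 1, shape = 1,
       c1_lo = -0.3, c1_hi = 1.6, c1_step = 0.005,
       n_start = 5L, n_max = 500L, stop_factor = 1.10,
       calibrate = TRUE, reps = 100000L, seed = 1L,
       nmax = 150L, format = "json")
}

validate_config <- function(raw) {
  defaults <- config_defaults()
  known <- c(names(defaults), "s0", "s1", "hr", "shape0", "shape1",
             "accrual", "p0", "p1", "out")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  probs <- c("alpha", "s0", "s1", "p0", "p1")
  for (key in probs) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0 || v >= 1))
      stop("config key `", key, "` must lie strictly between 0 and 1",
           call. = FALSE)
  }
  if (cfg$power <= 0 || cfg$power >= 1)
    stop("config key `power` must lie strictly between 0 and 1", call. = FALSE)
  for (key in c("tc", "accrual", "shape", "shape0", "shape1", "hr",
                "c1_step", "stop_factor")) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("config key `", key, "` must be positive", call. = FALSE)
  }
  if (!cfg$format %in% c("json", "csv"))
    stop("config key `format` must be 'json' or 'csv'", call. = FALSE)
  structure(cfg, class = c("surv2stage_config", "list"))
}

#' Write search or simulation results to disk
#'
#' Serialises the result of [surv2stage()], [simon2stage()],
#' [simulate_oc()] or [replicate_interval()] as a table whose columns
#' mirror the usual design-report layout (sample sizes, boundaries, PET,
#' `ESS0`, `ETSL0`, power). CSV output rounds floating point values to 4
#' decimals; JSON keeps full precision and embeds the result type. Output
#' is deterministic: identical inputs produce byte-identical files.
#'
#' @param x A result object.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 4)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    payload <- list(type = class(x)[1], results = df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @export
as.data.frame.surv2stage <- function(x, ...) {
  row <- function(d, label) {
    data.frame(design = label, n1 = d$n1, n = d$n, c1 = d$c1, c = d$c,
               PET = d$PET, ESS0 = d$ESS0, ETSL0 = d$ETSL0,
               power = d$power, tie = d$tie)
  }
  df <- rbind(row(x$minimax, "minimax"), row(x$optimal, "optimal"))
  if (!is.null(x$sim_power)) df$sim_power <- as.numeric(x$sim_power)
  df$adjustments <- x$adjustments
  df
}

#' @export
as.data.frame.simon2stage <- function(x, ...) {
  row <- function(d, label) {
    out <- data.frame(design = label, n1 = d$n1, r1 = d$r1, n = d$n, r = d$r,
                      PET = d$PET, ESS0 = d$ESS0, tie = d$tie,
                      power = d$power)
    if (!is.null(d$ETSL0)) {
      out$ETSL0 <- d$ETSL0
      out$ESS0_interim <- d$ESS0_interim
      out$ETSL0_interim <- d$ETSL0_interim
    }
    out
  }
  rbind(row(x$minimax, "minimax"), row(x$optimal, "optimal"))
}

#' @export
as.data.frame.surv2stage_sim <- function(x, ...) {
  df <- data.frame(n1 = x$design[["n1"]], n = x$design[["n"]],
                   c1 = x$design[["c1"]], c = x$design[["c"]],
                   under = x$under, reject = x$reject,
                   early_stop = x$early_stop, reps = x$reps)
  if (!is.null(x$interval)) {
    df$interval_lo <- x$interval[1]
    df$interval_hi <- x$interval[2]
  }
  df
}
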