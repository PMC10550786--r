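#' Load and validate a run configuration
#'
#' Builds a validated configuration from (in increasing precedence) the
#' built-in defaults, an optional flat YAML key-value file, and a list of
#' overrides (e.g. parsed command-line flags). All parameter violations are
#' reported together in a single error.
#'
#' Recognised keys: \code{F}, \code{a}, \code{G}, \code{omega}, \code{delta},
#' \code{p0}, \code{p}, \code{t_max}, \code{x_init}.
#'
#' @param file optional path to a flat YAML file of \code{key: value} pairs.
#' @param overrides named list of values that win over both the file and the
#'   defaults.
#' @return An object of class \code{"ps_config"}: a list with \code{eco}
#'   (\code{\link{eco_params}}), \code{pheno} (\code{\link{pheno_params}}),
#'   \code{p} (group composition for a single solve; defaults to \code{p0}),
#'   \code{t_max} and \code{x_init}.
#' @examples
#' cfg <- load_config()                    # all defaults
#' cfg$eco$a / cfg$eco$F                   # 0.2
#' cfg <- load_config(overrides = list(delta = 0.6))
#' @export
load_config <- function(file = NULL, overrides = list()) {
  values <- list(F = 10, a = 2, G = 10, omega = 0.8, delta = 0.8, p0 = 0.5,
                 p = NULL, t_max = 1000, x_init = 1)
  if (!is.null(file)) {
    if (!file.exists(file))
      stop(sprintf("configuration file not found: %s", file), call. = FALSE)
    from_file <- yaml::read_yaml(file)
    if (!is.list(from_file) || (length(from_file) && is.null(names(from_file))))
      stop("configuration file must be flat key: value pairs", call. = FALSE)
    unknown <- setdiff(names(from_file), names(values))
    if (length(unknown))
      stop(sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    values[names(from_file)] <- from_file
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(values))
    if (length(unknown))
      stop(sprintf("unknown option(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    values[names(overrides)] <- overrides
  }

  problems <- character()
  eco <- tryCatch(eco_params(values$F, values$a, values$G),
                  error = function(e) {
                    problems <<- c(problems, conditionMessage(e))
                    NULL
                  })
  pheno <- tryCatch(pheno_params(values$omega, values$delta, values$p0),
                    error = function(e) {
                      problems <<- c(problems, conditionMessage(e))
                      NULL
                    })
  if (!is.null(values$p) && !is_probability(values$p))
    problems <- c(problems, "`p` (strong frequency) must be in [0, 1]")
  if (!is_scalar_number(values$t_max) || values$t_max < 1)
    problems <- c(problems, "`t_max` must be a positive count")
  if (!is_probability(values$x_init))
    problems <- c(problems, "`x_init` must be in [0, 1]")
  if (length(problems))
    stop(paste(problems, collapse = "; "), call. = FALSE)

  structure(list(eco = eco, pheno = pheno,
                 p = if (is.null(values$p)) pheno$p0 else as.numeric(values$p),
                 t_max = as.integer(values$t_max),
                 x_init = as.numeric(values$x_init)),
            class = "ps_config")
}

#' Write a results table as CSV with full numeric precision
#'
#' Comma-separated, UTF-8, header row, \code{.} decimal, no row names.
#' Doubles are printed with \code{\%.17g}, so reading the file back
#' reproduces the values bit-for-bit.
#'
#' @param df a data frame.
#' @param path output file path, or \code{""} for standard output.
#' @return Invisibly, \code{path}.
#' @export
write_ps_csv <- function(df, path = "") {
  stopifnot(is.data.frame(df))
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, file = path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Command-line entry point
#'
#' Thin driver behind the \code{psgame} script. Subcommands: \code{solve}
#' (one Nash equilibrium at fixed composition), \code{evolve} (full
#' trajectory to the ESS), \code{sweep} (parameter sweep). Shared flags:
#' \code{--config}, \code{--out}, \code{--F}, \code{--a}, \code{--G},
#' \code{--omega}, \code{--delta}, \code{--p0}, \code{--quiet},
#' \code{--verbose}; \code{solve} adds \code{--p}; \code{evolve} adds
#' \code{--t-max}; \code{sweep} adds \code{--vary}, \code{--grid} (comma
#' separated) and \code{--mode}. Flags override configuration-file values.
#' Results go to \code{--out} (or standard output); diagnostics go to
#' standard error.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status: 0 on success, 1 on validation or solver
#'   failure.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' ps_main(c("solve", "--p", "0.5", "--out", tmp, "--quiet"))
#' read.csv(tmp)[, c("x_star", "y_star", "gamma")]
#' @export
ps_main <- function(argv = character()) {
  status <- tryCatch({
    run_cli(argv)
    0L
  }, error = function(e) {
    message("psgame error: ", conditionMessage(e))
    1L
  })
  status
}

run_cli <- function(argv) {
  if (!length(argv))
    stop("usage: psgame <solve|evolve|sweep> [--flags]", call. = FALSE)
  cmd <- argv[[1]]
  if (!cmd %in% c("solve", "evolve", "sweep"))
    stop(sprintf("unknown subcommand '%s' (expected solve, evolve or sweep)", cmd),
         call. = FALSE)
  opts <- parse_flags(argv[-1])
  verbosity <- if (isTRUE(opts$flags$quiet)) 0L
               else if (isTRUE(opts$flags$verbose)) 2L else 1L
  log_msg <- function(level, ...) if (verbosity >= level) message(sprintf(...))

  cfg_keys <- c("F", "a", "G", "omega", "delta", "p0", "p", "t_max", "x_init")
  overrides <- opts$values[intersect(names(opts$values), cfg_keys)]
  cfg <- load_config(file = opts$values$config, overrides = overrides)
  out <- if (is.null(opts$values$out)) "" else opts$values$out

  if (cmd == "solve") {
    eq <- solve_nash(cfg$eco, cfg$pheno, cfg$p, x_init = cfg$x_init)
    log_msg(1L, "solve: p = %g -> x* = %.10g, y* = %.10g, gamma = %.10g (%d sweeps, converged = %s)",
            cfg$p, eq$x_star, eq$y_star, eq$gamma, eq$iterations, eq$converged)
    if (!eq$converged) stop("best-reply dynamics did not converge", call. = FALSE)
    write_ps_csv(as.data.frame(eq), out)
  } else if (cmd == "evolve") {
    traj <- run_evolution(cfg$eco, cfg$pheno, t_max = cfg$t_max,
                          x_init = cfg$x_init)
    log_msg(1L, "evolve: %d steps%s; ESS p* = %.10g, x* = %.10g, y* = %.10g, gamma = %.10g",
            traj$steps_run, if (traj$ess_reached) " (ESS reached)" else "",
            traj$ess_p, traj$ess_x, traj$ess_y, traj$ess_gamma)
    write_ps_csv(traj$records, out)
  } else {
    if (is.null(opts$values$vary) || is.null(opts$values$grid))
      stop("sweep requires --vary and --grid", call. = FALSE)
    grid <- as.numeric(strsplit(opts$values$grid, ",", fixed = TRUE)[[1]])
    if (any(is.na(grid)))
      stop("--grid must be a comma-separated list of numbers", call. = FALSE)
    mode <- if (is.null(opts$values$mode)) "short_term" else opts$values$mode
    spec <- sweep_spec(opts$values$vary, grid, eco = cfg$eco,
                       pheno = cfg$pheno, mode = mode, t_max = cfg$t_max)
    log_msg(1L, "sweep: %s over %d values (%s mode)", spec$varied,
            length(grid), mode)
    tab <- run_sweep(spec)
    log_msg(2L, "sweep: %d/%d rows converged", sum(tab$converged), nrow(tab))
    write_ps_csv(tab, out)
  }
  invisible(NULL)
}

# --flag value pairs plus bare switches (--quiet/--verbose); numeric-looking
# values are converted. Returns list(values = named list, flags = switches).
parse_flags <- function(args) {
  values <- list()
  flags <- list(quiet = FALSE, verbose = FALSE)
  numeric_keys <- c("F", "a", "G", "omega", "delta", "p0", "p", "t_max", "x_init")
  i <- 1L
  while (i <= length(args)) {
    arg <- args[[i]]
    if (!startsWith(arg, "--"))
      stop(sprintf("unexpected argument '%s'", arg), call. = FALSE)
    key <- gsub("-", "_", substring(arg, 3))
    if (key %in% c("quiet", "verbose")) {
      flags[[key]] <- TRUE
      i <- i + 1L
      next
    }
    if (i == length(args))
      stop(sprintf("flag --%s needs a value", key), call. = FALSE)
    val <- args[[i + 1L]]
    if (key %in% numeric_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop(sprintf("flag --%s expects a number, got '%s'", key, val),
             call. = FALSE)
      val <- num
    }
    values[[key]] <- val
    i <- i + 2L
  }
  list(values = values, flags = flags)
}
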