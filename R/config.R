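#' Load and validate an experiment configuration
#'
#' Flat `key = value` text files (one pair per line, `#` comments allowed)
#' describing a complete experiment: model parameters, network, initial
#' placement and run settings.  Unknown keys are an error (fail-fast), as
#' are out-of-range values; the derived quantities (`delta_d`, the mean
#' abstention length, `d_min`) are echoed as a message.
#'
#' Recognized keys: `r` (or `r_min`/`r_max`/`r_step` for a sweep), `delta`,
#' `d`, `h`, `seed`, `network_model` (`ring4`, `square4`, `moore8`,
#' `single_scale`, `scale_free`, `holme_kim`, `complete`, `star`), `n`,
#' `mean_degree`, `transitivity`, `init_scheme`, `init_fraction` (or
#' `init_count`), `max_rounds`, `replicates`.
#'
#' @param path config file path.
#' @return A list with components `params` ([model_params()]),
#'   `network_spec` (for [network_from_spec()]), `init` (scheme and count
#'   or fraction), `run` (`max_rounds`, `replicates`, `r_grid`, `seed`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("unparseable config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  if (anyDuplicated(keys)) stop("duplicate config keys: ",
                                paste(unique(keys[duplicated(keys)]), collapse = ", "))
  allowed <- c("r", "r_min", "r_max", "r_step", "delta", "d", "h", "seed",
               "network_model", "n", "mean_degree", "transitivity",
               "init_scheme", "init_fraction", "init_count",
               "max_rounds", "replicates")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- setNames(as.list(vals), keys)
  num <- function(key, default = NULL) {
    if (is.null(cfg[[key]])) return(default)
    x <- suppressWarnings(as.numeric(cfg[[key]]))
    if (is.na(x) && !identical(tolower(cfg[[key]]), "inf")) {
      stop("config key `", key, "` is not numeric: ", cfg[[key]])
    }
    if (identical(tolower(cfg[[key]]), "inf")) Inf else x
  }
  chr <- function(key, default = NULL) {
    if (is.null(cfg[[key]])) default else cfg[[key]]
  }

  r_grid <- if (!is.null(cfg$r_min)) {
    if (is.null(cfg$r_max)) stop("r_min given without r_max")
    seq(num("r_min"), num("r_max"), by = num("r_step", 0.5))
  } else NULL
  r_ref <- if (!is.null(cfg$r)) num("r") else if (!is.null(r_grid)) r_grid[1L] else
    stop("config must set `r` or an `r_min`/`r_max` sweep range")

  params <- model_params(
    r = r_ref,
    delta = num("delta", 0.05),
    d = num("d", 0),
    h = num("h", 2)
  )

  model <- chr("network_model", "square4")
  lattices <- c("ring4", "square4", "moore8")
  network_spec <- if (model %in% lattices) {
    list(kind = "lattice", type = model, N = as.integer(num("n", 1024)))
  } else {
    list(kind = "random", model = model, N = as.integer(num("n", 1000)),
         mean_degree = num("mean_degree", 4),
         transitivity = num("transitivity", 0))
  }

  init <- list(
    scheme = chr("init_scheme", "random"),
    fraction = num("init_fraction", if (is.null(cfg$init_count)) 0.01 else NULL),
    count = if (!is.null(cfg$init_count)) as.integer(num("init_count")) else NULL
  )

  out <- list(
    params = params,
    network_spec = network_spec,
    init = init,
    run = list(
      max_rounds = as.integer(num("max_rounds", 10000)),
      replicates = as.integer(num("replicates", 20)),
      r_grid = r_grid,
      seed = if (!is.null(cfg$seed)) as.integer(num("seed")) else NULL
    )
  )
  message(sprintf(
    "config ok: delta_d = %g, <a> = %.4g rounds, admissible d in (%.4g, 1)",
    params$delta_d, mean_abstention_length(params$delta_d), params$d_min
  ))
  out
}
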