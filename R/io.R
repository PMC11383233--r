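# Configuration files, trajectory/summary writers, and run provenance.
#
# Config files are YAML with up to four blocks: `parameters` (any
# wb_params field), `integration` (t_end, dt, transient, thin), `analysis`
# (K_window, tau_valid, hom_margin) and `output` (dir, format). Unknown
# keys anywhere are rejected, all violations reported at once.

config_schema <- function() list(
  parameters = names(wb_params()),
  integration = c("t_end", "dt", "transient", "thin"),
  analysis = c("K_window", "tau_valid", "hom_margin"),
  output = c("dir", "format")
)

default_config <- function() {
  list(
    parameters = unclass(wb_params()),
    integration = list(t_end = 12000, dt = 0.005, transient = 2000,
                       thin = 10L),
    analysis = list(K_window = c(3, 16), tau_valid = 500, hom_margin = 2e-3),
    output = list(dir = ".", format = "csv")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it against the schema (unknown
#' keys and invalid values are all reported together, not first-failure),
#' and fills every unspecified entry with its default. An empty or missing
#' body yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A `wb_config` list with blocks `parameters` (a [wb_params()]
#'   object), `integration`, `analysis`, `output`, plus `hash`, a digest of
#'   the fully resolved configuration embedded in every output file.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(raw)) raw <- list()
  schema <- config_schema()
  problems <- character()
  bad_blocks <- setdiff(names(raw), names(schema))
  if (length(bad_blocks))
    problems <- c(problems, paste0("unknown block(s): ",
                                   paste(bad_blocks, collapse = ", ")))
  for (b in intersect(names(raw), names(schema))) {
    bad <- setdiff(names(raw[[b]]), schema[[b]])
    if (length(bad))
      problems <- c(problems, paste0("unknown key(s) in '", b, "': ",
                                     paste(bad, collapse = ", ")))
  }
  cfg <- default_config()
  for (b in intersect(names(raw), names(schema)))
    cfg[[b]] <- modifyList(cfg[[b]], raw[[b]][names(raw[[b]]) %in%
                                                schema[[b]]])
  params <- tryCatch(do.call(wb_params, cfg$parameters),
                     error = function(e) {
                       problems <<- c(problems, conditionMessage(e))
                       NULL
                     })
  if (!is.numeric(cfg$integration$dt) || cfg$integration$dt <= 0)
    problems <- c(problems, "integration$dt must be positive")
  if (!is.numeric(cfg$integration$t_end) ||
      cfg$integration$t_end <= cfg$integration$transient)
    problems <- c(problems, "integration$t_end must exceed the transient")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  cfg$parameters <- params
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "wb_config")
}

# md5 of the canonical JSON serialization of the resolved config
config_hash <- function(cfg) {
  cfg$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write and read trajectories as CSV
#'
#' Columns `t_ms`, `V_mV`, `h`, `n`, `Kout_mM` (and `Nain_mM` when sodium is
#' dynamic). Values are written with full (17 significant digit) precision,
#' so a read-back reproduces the trajectory bit-exactly. A header comment
#' embeds the configuration hash when one is supplied.
#'
#' @param traj A `wb_trajectory` (or compatible data frame).
#' @param path Output path.
#' @param hash Optional config hash to embed.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a tibble with the original column names (`t`, `V`, `h`, `n`,
#'   `K_out`, `Na_in`) and the embedded hash in attribute `hash`.
#' @export
write_trajectory <- function(traj, path, hash = NULL) {
  dir_ok(path)
  cols <- c(t = "t_ms", V = "V_mV", h = "h", n = "n", K_out = "Kout_mM",
            Na_in = "Nain_mM")
  use <- intersect(names(cols), names(traj))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_md5: ", hash), con)
  writeLines(paste(cols[use], collapse = ","), con)
  body <- vapply(use, function(cl) sprintf("%.17g", traj[[cl]]),
                 character(nrow(traj)))
  writeLines(do.call(paste, c(as.data.frame(body), sep = ",")), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  hash <- if (startsWith(first, "# config_md5: "))
    sub("# config_md5: ", "", first) else NULL
  df <- read.csv(path, comment.char = "#")
  back <- c(t_ms = "t", V_mV = "V", h = "h", n = "n", Kout_mM = "K_out",
            Nain_mM = "Na_in")
  names(df) <- unname(back[names(df)])
  structure(tibble::as_tibble(df), hash = hash)
}

#' Write a burst summary (or any one-row result) as JSON
#'
#' @param summary A tibble or list (list columns are flattened).
#' @param path Output path.
#' @param hash Optional config hash embedded under `config_md5`.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, hash = NULL) {
  dir_ok(path)
  x <- as.list(summary)
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(hash)) x$config_md5 <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# pre-flight: fail before computing if the directory is not writable
dir_ok <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) stop("output directory does not exist: ", d)
  if (file.access(d, 2) != 0) stop("output directory not writable: ", d)
  invisible(TRUE)
}

#' Dump the default parameter set
#'
#' Writes (or returns) the full default parameter table, the reproducibility
#' record for the model constants.
#'
#' @param path Optional YAML output path; when `NULL` the list is returned.
#' @return The parameter list, invisibly when written.
#' @export
params_dump <- function(path = NULL) {
  x <- unclass(wb_params())
  if (is.null(path)) return(x)
  dir_ok(path)
  yaml::write_yaml(list(parameters = x), path)
  invisible(x)
}
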