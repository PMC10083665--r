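#' Write a longitudinal clamp dataset to CSV
#'
#' Comma-separated, `.` decimal, UTF-8, fixed column order (`ID`, `OCC`,
#' `TIME`, `DVID`, `DV`, `BLQ`, `LOQ`, covariates). The output is
#' bit-stable: writing the same dataset twice produces identical files.
#'
#' @param data a `clamp_data` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  lead <- intersect(.required_cols, names(data))
  data <- data[c(lead, setdiff(names(data), lead))]
  write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a longitudinal clamp dataset from CSV
#'
#' Reads the dataset dialect written by [write_dataset()] and validates it:
#' required header, numeric fields, positive observations, BLQ consistency
#' (`BLQ = 1` requires `DV <= LOQ`), presence of a baseline (t = 0) record
#' per analyte and occasion, and a unit plausibility check (insulin above
#' 1000 uU/mL draws a warning).
#'
#' @param path CSV file path.
#' @return A `clamp_data` data.frame; the validation notes are in
#'   `attr(, "validation")`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.required_cols, names(d))
  if (length(miss))
    stop("header lacks column(s): ", paste(miss, collapse = ", "))
  for (nm in c("ID", "OCC", "TIME", "DVID", "DV", "BLQ")) {
    if (!is.numeric(d[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[nm]]))))[1]
      stop("malformed value in column ", nm, " at data line ", bad)
    }
  }
  if (!all(d$DVID %in% 1:5))
    stop("malformed DVID at data line ", which(!(d$DVID %in% 1:5))[1])
  if (any(d$DV <= 0))
    stop("non-positive DV at data line ", which(d$DV <= 0)[1])
  obs <- d$DVID %in% 1:3
  if (!any(obs)) stop("empty dataset: no hormone observation records")
  bad_blq <- d$BLQ == 1 & !is.na(d$LOQ) & d$DV > d$LOQ
  if (any(bad_blq))
    stop("BLQ flag inconsistent with LOQ at data line ", which(bad_blq)[1])
  notes <- character()
  if (any(d$DVID == 5 & d$DV > 1000)) {
    warning("insulin above 1000 uU/mL: check units")
    notes <- c(notes, "insulin>1000")
  }
  key <- unique(d[obs, c("ID", "OCC", "DVID")])
  has0 <- mapply(function(i, o, a)
    any(d$ID == i & d$OCC == o & d$DVID == a & d$TIME == 0),
    key$ID, key$OCC, key$DVID)
  if (!all(has0))
    notes <- c(notes, paste0("missing baseline record for ",
                             sum(!has0), " analyte-occasion(s)"))
  attr(d, "validation") <- notes
  class(d) <- c("clamp_data", "data.frame")
  d
}

.allowed_keys <- list(
  common = c("command", "seed", "out_dir", "params"),
  simulate = c("design", "n", "bsv", "bov", "residual", "jitter_sd"),
  fit = c("data", "submodel", "structure", "delay", "n_starts"),
  vpc = c("data", "nsim", "bin"),
  thresholds = c("gir", "target"),
  scm = c("data", "candidates", "forward_alpha", "backward_alpha"))

#' Run a pipeline stage from a configuration
#'
#' Thin orchestration layer over the package functions: executes one of the
#' commands `simulate`, `fit`, `vpc`, `thresholds` or `scm` described by a
#' configuration list (or YAML file), writes its artifacts into the output
#' directory and appends a run log recording the seed, a parameter
#' fingerprint and the package version. A seed is mandatory for every
#' stochastic command; unknown configuration keys are rejected.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Common keys: `command`, `seed`, `out_dir`, `params` (YAML file or
#'   named list of [hormone_params()] overrides). Per command:
#'   `simulate`: `design` (preset name(s)), `n`, `bsv`/`bov`/`residual`,
#'   `jitter_sd`; `fit`: `data`, `submodel`, `structure`, `delay`,
#'   `n_starts`; `vpc`: `data`, `nsim`, `bin`; `thresholds`: `gir`
#'   (vector, default 12.0 and 4.5), `target` (default 0.9); `scm`:
#'   `data`, `candidates` (strings `"parameter:COVARIATE"`),
#'   `forward_alpha`, `backward_alpha`.
#' @return Invisibly, a list with `status = 0` and the paths written.
#' @export
counterreg_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$command)) stop("config lacks 'command'")
  cmd <- match.arg(config$command,
                   c("simulate", "fit", "vpc", "thresholds", "scm"))
  allowed <- c(.allowed_keys$common, .allowed_keys[[cmd]])
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (cmd != "thresholds" && is.null(config$seed))
    stop("'seed' is mandatory for stochastic commands")
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- if (is.null(config$params)) hormone_params()
       else if (is.character(config$params))
         do.call(hormone_params, yaml::read_yaml(config$params))
       else do.call(hormone_params, config$params)
  files <- character()
  emit <- function(name) file.path(out_dir, name)

  if (cmd == "simulate") {
    n <- if (is.null(config$n)) 10L else config$n
    des <- if (is.null(config$design)) "almby" else config$design
    fargs <- if (is.null(config$jitter_sd)) list()
             else list(jitter_sd = config$jitter_sd)
    d <- generate_dataset(des, n = n, p = p,
                          bsv = !isFALSE(config$bsv),
                          bov = !isFALSE(config$bov),
                          residual = !isFALSE(config$residual),
                          seed = config$seed, forcing_args = fargs)
    files <- emit("dataset.csv")
    write_dataset(d, files)
  } else if (cmd == "fit") {
    d <- read_dataset(config$data)
    v <- model_variant(
      structure = if (is.null(config$structure)) "turnover"
                  else config$structure,
      delay = !isFALSE(config$delay))
    ns <- if (is.null(config$n_starts)) 5 else config$n_starts
    f <- fit_submodel(d, config$submodel, variant = v, n_starts = ns,
                      seed = config$seed)
    files <- emit("fit.json")
    jsonlite::write_json(list(submodel = f$submodel, ofv = f$ofv,
                              estimates = f$estimates[f$free],
                              convergence = f$convergence,
                              n_obs = f$n_obs, seed = f$seed),
                         files, auto_unbox = TRUE, digits = NA)
  } else if (cmd == "vpc") {
    d <- read_dataset(config$data)
    nsim <- if (is.null(config$nsim)) 1000 else config$nsim
    bin <- if (is.null(config$bin)) "glucose" else config$bin
    v <- vpc(d, p, n_sim = nsim, bin_by = bin, seed = config$seed)
    files <- c(emit("vpc.csv"), emit("vpc_blq.csv"))
    write.csv(v$stats, files[1], row.names = FALSE)
    write.csv(v$blq, files[2], row.names = FALSE)
  } else if (cmd == "thresholds") {
    gir <- if (is.null(config$gir)) c(12.0, 4.5) else config$gir
    target <- if (is.null(config$target)) 0.9 else config$target
    tab <- rbind(
      data.frame(measure = sprintf("glucose for %.0f%% ACTH inhibition",
                                   100 * target),
                 gir = gir,
                 value = glucose_for_acth_inhibition(target, gir, p),
                 units = "mmol/L"),
      data.frame(measure = "glucose for 50% ACTH response",
                 gir = gir,
                 value = glucose_for_acth_half_response(gir, p),
                 units = "mmol/L"),
      data.frame(measure = sprintf(
        "insulin for %.0f%% glucagon inhibition at 5 mmol/L", 100 * target),
        gir = gir,
        value = insulin_for_glucagon_inhibition(target, 5.0, gir, p),
        units = "uU/mL"))
    files <- emit("thresholds.csv")
    write.csv(tab, files, row.names = FALSE)
  } else if (cmd == "scm") {
    d <- read_dataset(config$data)
    cand <- do.call(rbind, lapply(config$candidates, function(s) {
      z <- strsplit(s, ":", fixed = TRUE)[[1]]
      data.frame(parameter = z[1], covariate = z[2])
    }))
    fa <- if (is.null(config$forward_alpha)) 0.05 else config$forward_alpha
    ba <- if (is.null(config$backward_alpha)) 0.01 else config$backward_alpha
    res <- scm(d, cand, forward_alpha = fa, backward_alpha = ba,
               seed = config$seed)
    files <- emit("scm.json")
    jsonlite::write_json(list(selected = res$selected, trace = res$trace,
                              collinear = res$collinear),
                         files, auto_unbox = TRUE, digits = NA)
  }

  phash <- signif(sum(unlist(p[!(names(p) %in% c("bsv", "bov"))])) +
                    sum(p$bsv) + sum(p$bov), 12)
  log_line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " command=",
                     cmd, " seed=", if (is.null(config$seed)) "NA"
                     else config$seed,
                     " param_hash=", phash,
                     " version=", as.character(packageVersion("counterreg")))
  cat(log_line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
  invisible(list(status = 0L, files = files,
                 log = file.path(out_dir, "run.log")))
}
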