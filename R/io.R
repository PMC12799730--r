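the_cache <- new.env(parent = emptyenv())

#' Load a packaged reference parameter set
#'
#' Returns one of the packaged parameterizations of the two-codon system:
#' `"baseline"` (equal tRNA pools, 1250/1250), `"ratio07"` (1750 preferred /
#' 750 non-preferred), or `"ratio09"` (2250/250). All sets share the
#' reference species counts (2500 tRNAs, 500 ribosomes, 100 transcripts of
#' 300 codons) and `k_speed = 0.02`; `k_charge` and `k_bind_eff` are the
#' values calibrated — once per session, via [calibrate_rates()] on the
#' equal-pool baseline — against the observed 88% charged-tRNA and 88%
#' active-ribosome fractions.
#'
#' @param name One of `"baseline"`, `"ratio07"`, `"ratio09"`.
#' @param ... Optional field overrides passed to [update_params()] (e.g.
#'   `k_charge = 3`, `f_op = 0.7`).
#' @return A `codon_params` object.
#' @examples
#' load_reference_params("ratio07", k_charge = 3)
#' @export
load_reference_params <- function(name = c("baseline", "ratio07", "ratio09"),
                                  ...) {
  ref <- reference_table()
  if (!is.character(name) || length(name) != 1 || !name %in% names(ref$ratios)) {
    stop("unknown reference set '", paste(name, collapse = ","),
         "'; available: ", paste(names(ref$ratios), collapse = ", "),
         call. = FALSE)
  }
  cal <- calibrated_baseline()
  frac <- ref$ratios[[name]]
  p <- two_codon_params(
    T1_tot = round(frac * ref$T_tot), T2_tot = round((1 - frac) * ref$T_tot),
    R_tot = ref$R_tot, N = ref$N, L = ref$L,
    k_charge = cal$k_charge, k_speed = ref$k_speed,
    k_bind_eff = cal$k_bind_eff, f_op = 0.5
  )
  if (...length() > 0) p <- update_params(p, ...)
  p
}

reference_table <- function() {
  if (is.null(the_cache$ref)) {
    path <- system.file("extdata", "table2.yaml", package = "twocodon",
                        mustWork = TRUE)
    the_cache$ref <- yaml::read_yaml(path)
  }
  the_cache$ref
}

calibrated_baseline <- function() {
  if (is.null(the_cache$cal)) {
    ref <- reference_table()
    template <- two_codon_params(
      T1_tot = ref$T_tot / 2, T2_tot = ref$T_tot / 2,
      R_tot = ref$R_tot, N = ref$N, L = ref$L,
      k_charge = 1, k_speed = ref$k_speed, k_bind_eff = 1e-3, f_op = 0.5
    )
    the_cache$cal <- calibrate_rates(
      template,
      target_charged_frac = ref$calibration_targets$charged_frac,
      target_active_frac = ref$calibration_targets$active_frac
    )
  }
  the_cache$cal
}

#' Read / write model parameters as YAML or JSON
#'
#' Parameter files carry exactly the nine model fields (`T1_tot`, `T2_tot`,
#' `R_tot`, `N`, `L`, `k_charge`, `k_speed`, `k_bind_eff`, `f_op`); unknown
#' keys are rejected. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @param params A `codon_params` object.
#' @return `read_params()` returns a `codon_params`; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- switch(file_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE)
  )
  # YAML 1.1 reads a bare `N` key as a boolean; map it back
  names(vals)[names(vals) == "FALSE"] <- "N"
  fields <- c("T1_tot", "T2_tot", "R_tot", "N", "L",
              "k_charge", "k_speed", "k_bind_eff", "f_op")
  unknown <- setdiff(names(vals), fields)
  if (length(unknown) > 0) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(two_codon_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  vals <- unclass(params)
  switch(file_format(path),
    yaml = yaml::write_yaml(vals, path, precision = 15),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  )
  invisible(path)
}

file_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("unsupported parameter file extension '.", ext,
       "' (use .yaml, .yml or .json)", call. = FALSE)
}

#' Write a result table with a provenance header
#'
#' Prepends comment lines (`#`) carrying the package version and the fully
#' resolved run configuration (as compact JSON) to a CSV table, so any
#' result file can be regenerated exactly from its own header. No timestamp
#' is included: identical configuration and seed produce byte-identical
#' files.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param config Named list describing the run (subcommand, parameters,
#'   options, seed).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(df, path, config = list()) {
  header <- c(
    sprintf("# twocodon %s", as.character(utils::packageVersion("twocodon"))),
    sprintf("# config: %s",
            jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}
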