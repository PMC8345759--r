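#' Load and validate the pipeline configuration
#'
#' Reads a YAML configuration holding the NRF9.3 nutrient reference values,
#' AMDR bounds, serving sizes per core food group, the four reference
#' household members with their recommended servings and requirements,
#' income table, substitution rules, and diet-quality-index component
#' tables. Omitted optional keys are filled from package defaults.
#'
#' The NRF9.3 basket is fixed: nine qualifying nutrients (protein, fiber,
#' vitamins A, C and E, calcium, iron, magnesium, potassium) each with a
#' positive daily value, and three limiting nutrients (saturated fat, added
#' sugars, sodium) each with a positive maximum reference value.
#'
#' @param config_path Path to a YAML file; `NULL` loads the shipped default.
#' @return A validated configuration object of class `diet_config`.
#' @export
#' @examples
#' cfg <- validate_config()
#' names(cfg$nrf$qualifying)
validate_config <- function(config_path = NULL) {
  if (is.null(config_path)) {
    config_path <- system.file("extdata", "default_config.yaml",
                               package = "dietsub", mustWork = TRUE)
  }
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  raw <- yaml::read_yaml(config_path)
  defaults <- list(gst_rate = 0.15, oecd_factor = 2,
                   discretionary_serving_kcal = 150,
                   discretionary_limit_per_day = 11)
  for (key in names(defaults)) {
    if (is.null(raw[[key]])) {
      raw[[key]] <- defaults[[key]]
      message("config: `", key, "` omitted; default ", defaults[[key]],
              " used")
    }
  }

  q <- raw$nrf$qualifying
  l <- raw$nrf$limiting
  missing_q <- setdiff(NRF_QUALIFYING, names(q))
  missing_l <- setdiff(NRF_LIMITING, names(l))
  if (length(missing_q) || length(missing_l)) {
    stop("config missing NRF nutrient(s): ",
         paste(c(missing_q, missing_l), collapse = ", "), call. = FALSE)
  }
  ref <- unlist(c(q[NRF_QUALIFYING], l[NRF_LIMITING]))
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    bad <- names(ref)[!is.finite(ref) | ref <= 0]
    stop("non-positive NRF reference value for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  for (key in c("serving_sizes_g", "members", "incomes", "heifa", "dice")) {
    if (is.null(raw[[key]])) {
      stop("config missing required section `", key, "`", call. = FALSE)
    }
  }
  ss <- unlist(raw$serving_sizes_g)
  if (any(ss <= 0)) stop("serving sizes must be positive", call. = FALSE)
  if (raw$gst_rate < 0 || raw$gst_rate >= 1) {
    stop("gst_rate must be in [0, 1)", call. = FALSE)
  }
  for (idx in c("heifa", "dice")) {
    tot <- sum(vapply(raw[[idx]]$components, function(x) x$max, numeric(1)))
    if (abs(tot - 100) > 1e-8) {
      stop("`", idx, "` component maxima must sum to 100 (got ", tot, ")",
           call. = FALSE)
    }
  }
  structure(raw, class = "diet_config")
}

#' @export
print.diet_config <- function(x, ...) {
  cat("<diet_config>\n")
  cat("  NRF qualifying:", paste(names(x$nrf$qualifying), collapse = ", "),
      "\n")
  cat("  NRF limiting:  ", paste(names(x$nrf$limiting), collapse = ", "),
      "\n")
  cat("  members:", length(x$members),
      "| gst_rate:", x$gst_rate,
      "| oecd_factor:", x$oecd_factor, "\n")
  invisible(x)
}
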