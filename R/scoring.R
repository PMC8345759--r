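#' Adult diet-quality score (HEIFA-2013-style, 11 components)
#'
#' Scores a single adult's diet out of 100 across the configured eleven
#' components: five core food groups scored proportionally to
#' servings/recommendation (capped at the component maximum), a
#' discretionary-foods component declining linearly with discretionary
#' intake, three negative-nutrient components (saturated fat and added
#' sugars as percent of energy, sodium in mg/day) scored by threshold
#' bands, and water and alcohol fixed at their maxima because those
#' intakes are outside the model.
#'
#' @param diet A per-member `diet_profile`, or `NULL` for an empty diet
#'   (scores the fixed components only).
#' @param member The member definition from the config (supplies
#'   `recommended_servings`).
#' @param config A `diet_config`.
#' @return A `dqi_result`: `total`, `components` tibble, `fixed_components`.
#' @export
score_heifa <- function(diet, member, config) {
  score_dqi(diet, member, config, config$heifa$components, "HEIFA")
}

#' Child diet-quality score (DICE-style, 13 components)
#'
#' As [score_heifa()] but with the thirteen-component child structure:
#' five core food groups, fruit-and-vegetable variety, wholegrain share of
#' grain servings, low-fat/low-sugar/low-salt band components, and water,
#' tea/coffee and eating-patterns components fixed at their maxima.
#'
#' @inheritParams score_heifa
#' @return A `dqi_result`.
#' @export
score_dice <- function(diet, member, config) {
  score_dqi(diet, member, config, config$dice$components, "DICE")
}

score_dqi <- function(diet, member, config, components, index) {
  rec <- unlist(member$recommended_servings)
  empty <- is.null(diet) || diet$energy_kcal_day <= 0
  basis_value <- function(basis) {
    switch(basis,
           satfat_percent_energy = unname(diet$macro_percent_energy["satfat"]),
           added_sugars_percent_energy =
             unname(diet$macro_percent_energy["added_sugars"]),
           sodium_mg_day = unname(diet$nutrients_day["sodium"]),
           stop("unknown band basis: ", basis, call. = FALSE))
  }
  rows <- lapply(names(components), function(nm) {
    comp <- components[[nm]]
    if (is.null(comp$max) || is.null(comp$type)) {
      stop("component `", nm, "` missing max/type config", call. = FALSE)
    }
    basis <- NA_real_
    pts <- switch(
      comp$type,
      fixed = comp$max,
      food_group = {
        if (empty) 0 else {
          if (is.na(rec[nm])) stop("no recommendation for group ", nm,
                                   call. = FALSE)
          basis <- unname(diet$servings_by_group[nm])
          comp$max * min(basis / rec[nm], 1)
        }
      },
      discretionary = {
        if (empty) 0 else {
          basis <- diet$discretionary_servings_day
          limit <- config$discretionary_limit_per_day /
            length(config$members)
          comp$max * max(0, 1 - basis / limit)
        }
      },
      band = {
        if (empty) 0 else {
          basis <- basis_value(comp$basis)
          band_points(basis, comp$bands, comp$max)
        }
      },
      variety = {
        if (empty) 0 else {
          sv <- diet$servings
          basis <- sum(sv$core_group %in% c("fruit", "vegetables") &
                         !sv$discretionary & sv$servings_day > 0)
          comp$max * min(basis / comp$target, 1)
        }
      },
      wholegrain = {
        if (empty) 0 else {
          sv <- diet$servings[!diet$servings$discretionary &
                                diet$servings$core_group == "grains", ]
          total <- sum(sv$servings_day)
          pat <- paste(config$wholegrain_patterns, collapse = "|")
          wg <- sum(sv$servings_day[grepl(pat, tolower(sv$name))])
          basis <- if (total > 0) wg / total else 0
          comp$max * basis
        }
      },
      stop("unknown component type: ", comp$type, call. = FALSE))
    tibble::tibble(component = nm, points = pts, max_points = comp$max,
                   basis = basis)
  })
  components_tbl <- dplyr::bind_rows(rows)
  fixed <- names(components)[vapply(components,
                                    function(c) c$type == "fixed",
                                    logical(1))]
  structure(list(index = index,
                 total = sum(components_tbl$points),
                 components = components_tbl,
                 fixed_components = fixed),
            class = "dqi_result")
}

# Threshold bands: below bands[1] full points, below bands[2] half, else 0.
band_points <- function(value, bands, max_points) {
  if (value < bands[1]) max_points
  else if (value < bands[2]) max_points / 2
  else 0
}

#' @export
print.dqi_result <- function(x, ...) {
  cat("<dqi_result> ", x$index, " total ", round(x$total, 1), "/100 (",
      nrow(x$components), " components)\n", sep = "")
  invisible(x)
}
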