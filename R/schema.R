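#' Tier schemas: typed variables, temporal tiers and forbidden orientations
#'
#' A tier schema is the background-knowledge object of the package. It fixes
#' the set of variables, their measurement type (continuous or categorical
#' with ordered levels), their position in the temporal ordering of the
#' cohort (the *tier*), and an optional list of pairwise orientations that
#' are prohibited a priori (an entry `(a, b)` forbids the edge `a -> b`).
#'
#' Edges learned by [run_tpc()] may never point from a later tier into an
#' earlier one, and never along a forbidden orientation.
#'
#' @param variables A data frame with columns `name` (character), `kind`
#'   (`"continuous"` or `"categorical"`), `tier` (non-negative integer index
#'   into `tiers`) and, for categorical variables, a list-column `levels`
#'   of character vectors with at least two entries.
#' @param tiers Character vector of ordered tier labels.
#' @param forbidden Data frame with columns `from`, `to`: orientations
#'   `from -> to` that must not appear. May be empty.
#' @return An object of class `tier_schema`.
#' @examples
#' sch <- tier_schema(
#'   variables = tibble::tibble(
#'     name = c("sex", "bmi"),
#'     kind = c("categorical", "continuous"),
#'     tier = c(0L, 1L),
#'     levels = list(c("female", "male"), NULL)
#'   ),
#'   tiers = c("context", "baseline")
#' )
#' n_variables(sch)
#' @export
tier_schema <- function(variables, tiers, forbidden = NULL) {
  variables <- as_tibble(variables)
  stopifnot(all(c("name", "kind", "tier") %in% names(variables)))
  if (!"levels" %in% names(variables)) variables$levels <- vector("list", nrow(variables))
  variables$tier <- as.integer(variables$tier)
  if (anyDuplicated(variables$name)) abort("variable names must be unique")
  if (!all(variables$kind %in% c("continuous", "categorical"))) {
    abort("`kind` must be 'continuous' or 'categorical'")
  }
  bad_cat <- variables$kind == "categorical" &
    !vapply(variables$levels, function(l) length(l) >= 2, logical(1))
  if (any(bad_cat)) abort("categorical variables need >= 2 levels")
  bad_cont <- variables$kind == "continuous" &
    vapply(variables$levels, function(l) length(l) > 0, logical(1))
  if (any(bad_cont)) abort("continuous variables must not declare levels")
  if (any(variables$tier < 0) || any(variables$tier >= length(tiers))) {
    abort("every variable tier index must lie in [0, number of tiers)")
  }
  if (is.null(forbidden)) forbidden <- tibble(from = character(), to = character())
  forbidden <- as_tibble(forbidden)[, c("from", "to")]
  unknown <- setdiff(c(forbidden$from, forbidden$to), variables$name)
  if (length(unknown)) {
    abort(sprintf("forbidden pairs mention unknown variables: %s",
                  paste(unknown, collapse = ", ")))
  }
  structure(
    list(variables = variables, tiers = as.character(tiers), forbidden = forbidden),
    class = "tier_schema"
  )
}

#' @export
print.tier_schema <- function(x, ...) {
  cat(sprintf("<tier_schema> %d variables in %d tiers, %d forbidden orientation(s)\n",
              nrow(x$variables), length(x$tiers), nrow(x$forbidden)))
  tab <- table(factor(x$tiers[x$variables$tier + 1L], levels = x$tiers))
  for (i in seq_along(tab)) cat(sprintf("  [%d] %s: %d\n", i - 1L, names(tab)[i], tab[i]))
  invisible(x)
}

#' @rdname tier_schema
#' @param schema A `tier_schema`.
#' @export
n_variables <- function(schema) nrow(schema$variables)

# named integer vector of tier indices
schema_tiers <- function(schema) {
  setNames(schema$variables$tier, schema$variables$name)
}

schema_kinds <- function(schema) {
  setNames(schema$variables$kind, schema$variables$name)
}

schema_levels <- function(schema) {
  setNames(schema$variables$levels, schema$variables$name)
}

#' Fixture schema emulating a three-wave European children's cohort
#'
#' Returns the package's reference schema: 51 mixed-type variables observed
#' over a life-course design with eight ordered tiers -- sociodemographic
#' context (sex, region, migration background), parental education/income
#' before baseline, seven early-life factors (pregnancy, birth and infant
#' feeding variables), the remaining baseline measurements, then
#' education/income and the remaining measurements at each of two follow-up
#' waves. Variable kinds (19 categorical, 32 continuous) mirror the cohort
#' code book; the forbidden list ships the one orientation that is
#' prohibited on subject-matter grounds beyond the tier ordering itself:
#' breastfeeding duration can not influence birthweight.
#'
#' @param extra_forbidden Optional data frame with columns `from`, `to` of
#'   additional prohibited orientations to merge into the fixture.
#' @return A [tier_schema()].
#' @examples
#' sch <- idefics_schema()
#' n_variables(sch)  # 51
#' @export
idefics_schema <- function(extra_forbidden = NULL) {
  yn <- c("no", "yes")
  lmh <- c("low", "middle", "high")
  school <- c("kindergarten", "school", "neither")
  v <- function(name, kind, tier, levels = NULL) {
    tibble(name = name, kind = kind, tier = tier, levels = list(levels))
  }
  wave <- function(suffix, tier, with_school) {
    out <- list(
      v(paste0("age_", suffix), "continuous", tier),
      v(paste0("avm_", suffix), "continuous", tier),
      v(paste0("zbmi_", suffix), "continuous", tier),
      v(paste0("mother_bmi_", suffix), "continuous", tier),
      v(paste0("family_meals_", suffix), "categorical", tier, yn),
      v(paste0("pa_", suffix), "continuous", tier),
      v(paste0("sleep_", suffix), "continuous", tier),
      v(paste0("wellbeing_", suffix), "continuous", tier),
      v(paste0("yhei_", suffix), "continuous", tier),
      v(paste0("homa_", suffix), "continuous", tier)
    )
    if (with_school) out <- c(out, list(v(paste0("school_", suffix), "categorical", tier, school)))
    dplyr::bind_rows(out)
  }
  variables <- dplyr::bind_rows(
    v("sex", "categorical", 0L, c("female", "male")),
    v("region", "categorical", 0L, c("north", "central", "south")),
    v("migrant", "categorical", 0L, yn),
    v("isced_b", "categorical", 1L, lmh),
    v("income_b", "categorical", 1L, lmh),
    v("mother_age_birth", "continuous", 2L),
    v("total_breastfeeding", "continuous", 2L),
    v("birthweight", "continuous", 2L),
    v("weeks_pregnancy", "continuous", 2L),
    v("formula_milk", "categorical", 2L, yn),
    v("hh_diet", "continuous", 2L),
    v("smoking_pregnancy", "categorical", 2L, yn),
    wave("b", 3L, with_school = TRUE),
    v("isced_fu1", "categorical", 4L, lmh),
    v("income_fu1", "categorical", 4L, lmh),
    wave("fu1", 5L, with_school = TRUE),
    v("isced_fu2", "categorical", 6L, lmh),
    v("income_fu2", "categorical", 6L, lmh),
    wave("fu2", 7L, with_school = FALSE),
    v("alcohol_fu2", "categorical", 7L, yn),
    v("puberty_fu2", "categorical", 7L, c("pre_early", "pubertal")),
    v("smoking_fu2", "categorical", 7L, yn)
  )
  forbidden <- tibble(from = "total_breastfeeding", to = "birthweight")
  if (!is.null(extra_forbidden)) {
    forbidden <- dplyr::distinct(dplyr::bind_rows(forbidden, as_tibble(extra_forbidden)))
  }
  tier_schema(
    variables,
    tiers = c("context", "education_income_b", "early_life", "baseline",
              "education_income_fu1", "fu1", "education_income_fu2", "fu2"),
    forbidden = forbidden
  )
}

#' Read or write a tier schema as YAML or JSON
#'
#' The on-disk form has top-level keys `tiers`, `variables` (each with
#' `name`, `kind`, `tier` and, for categoricals, `levels`) and `forbidden`
#' (list of `from`/`to` pairs). The format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path File path.
#' @return `read_schema()` returns a [tier_schema()]; `write_schema()`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  vars <- purrr::map_dfr(obj$variables, function(v) {
    tibble(name = v$name, kind = v$kind, tier = as.integer(v$tier),
           levels = list(if (is.null(v$levels)) NULL else unlist(v$levels)))
  })
  forb <- if (length(obj$forbidden)) {
    purrr::map_dfr(obj$forbidden, ~ tibble(from = .x$from, to = .x$to))
  } else NULL
  tier_schema(vars, tiers = unlist(obj$tiers), forbidden = forb)
}

#' @rdname read_schema
#' @param schema A [tier_schema()].
#' @export
write_schema <- function(schema, path) {
  obj <- list(
    tiers = as.list(schema$tiers),
    variables = purrr::pmap(schema$variables, function(name, kind, tier, levels) {
      out <- list(name = name, kind = kind, tier = tier)
      if (kind == "categorical") out$levels <- as.list(levels)
      out
    }),
    forbidden = purrr::pmap(schema$forbidden, function(from, to) list(from = from, to = to))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
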