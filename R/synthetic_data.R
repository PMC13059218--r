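# Synthetic survey / register / crosswalk generator with exact ground truth.
#
# Responses are generated by a two-point construction: an "exposed" draw lands
# uniformly on the aligned values strictly above the intended cut-off, a
# "non-exposed" draw uniformly on the values at or below it, so that
# P(aligned value > cut-off) equals the cell's true exposure probability
# exactly. Downstream share-recovery tests therefore have exact ground truth;
# the analysis only ever uses the dichotomized variable.

#' Define a simulation scenario
#'
#' The scenario defaults mirror the structure of the five Norwegian
#' living-conditions work-environment survey waves the method was developed
#' on: 333 occupation codes grouped into 268 JEM groups, waves 2006, 2009,
#' 2013, 2016 and 2019, and 16 respondents per (group, gender, wave) cell —
#' about 43,000 respondents in total. `intended_cutoff` is the median the
#' generator targets on the aligned 1–5 scale; provided the mean true
#' exposure probability stays below 0.5 the pooled empirical median equals
#' it, so the full pipeline recovers the generating probabilities.
#'
#' @param n_codes number of distinct 4-digit occupation codes.
#' @param n_groups number of JEM groups (`n_groups <= n_codes`; every group
#'   receives at least one code).
#' @param waves survey years.
#' @param n_per_cell respondents per (group, gender, wave) cell.
#' @param true_exposure_prob optional tibble `(jem_group_id, gender, item_id,
#'   prob)`; when `NULL`, probabilities are drawn uniformly on
#'   \[0.05, 0.45\] per cell and item (deterministically from `seed`) and
#'   returned with the survey.
#' @param scale_max top of the ordinal response scale.
#' @param intended_cutoff target median on the aligned scale; exposed draws
#'   lie strictly above it.
#' @param missing_rate probability that any single response is missing
#'   (missing completely at random).
#' @param seed integer seed; all generator output is reproducible from it.
#' @return a `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_codes = 333L, n_groups = 268L,
                                waves = c(2006L, 2009L, 2013L, 2016L, 2019L),
                                n_per_cell = 16L,
                                true_exposure_prob = NULL,
                                scale_max = 5L, intended_cutoff = 2L,
                                missing_rate = 0.02, seed = 20061L) {
  n_codes <- as.integer(n_codes); n_groups <- as.integer(n_groups)
  if (n_groups > n_codes) stop("n_groups must be <= n_codes", call. = FALSE)
  if (n_codes < 1L) stop("need at least one occupation code", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(true_exposure_prob)) {
    true_exposure_prob <- as_tibble(true_exposure_prob)
    need <- c("jem_group_id", "gender", "item_id", "prob")
    if (!all(need %in% names(true_exposure_prob))) {
      stop("true_exposure_prob needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(true_exposure_prob$prob < 0 | true_exposure_prob$prob > 1)) {
      stop("true_exposure_prob values must lie in [0, 1]", call. = FALSE)
    }
  }
  if (intended_cutoff >= scale_max) {
    stop("intended_cutoff must be below scale_max", call. = FALSE)
  }
  structure(list(n_codes = n_codes, n_groups = n_groups,
                 waves = as.integer(waves), n_per_cell = as.integer(n_per_cell),
                 true_exposure_prob = true_exposure_prob,
                 scale_max = as.integer(scale_max),
                 intended_cutoff = as.integer(intended_cutoff),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(paste0("<simulation_scenario> %d codes / %d groups, %d wave(s),",
                     " %d per cell, missing %.1f%%, seed %d\n"),
              x$n_codes, x$n_groups, length(x$waves), x$n_per_cell,
              100 * x$missing_rate, x$seed))
  invisible(x)
}

#' Deterministic occupation-code to JEM-group map for a scenario
#'
#' Codes are 4-digit strings sampled without replacement; the first
#' `n_groups` codes seed one group each (so no group is empty) and the rest
#' are assigned to groups at random.
#'
#' @param scenario a [simulation_scenario()].
#' @return a [jem_group_map()].
#' @export
scenario_group_map <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  withr::with_seed(scenario$seed, {
    codes <- sprintf("%04d", sample(100:9999, scenario$n_codes))
    groups <- sprintf("G%03d", seq_len(scenario$n_groups))
    extra <- scenario$n_codes - scenario$n_groups
    assignment <- c(seq_len(scenario$n_groups),
                    if (extra > 0L) sample(scenario$n_groups, extra,
                                           replace = TRUE))
    jem_group_map(tibble(occupation_code = codes,
                         jem_group_id = groups[assignment]))
  })
}

#' Generate survey microdata with known exposure structure
#'
#' For every (JEM group, gender, wave) cell, `n_per_cell` respondents are
#' generated; each respondent's occupation code is sampled among the codes of
#' their group. Responses are drawn so that the probability of the aligned
#' value strictly exceeding `intended_cutoff` equals the cell's true exposure
#' probability exactly, independently across respondents and items. Items
#' with `adverse_high = FALSE` are stored on the raw (reflected) scale, so
#' the generator exercises orientation alignment downstream. Missing
#' responses are injected completely at random at `missing_rate`.
#'
#' @param scenario a [simulation_scenario()].
#' @param item_set an [item_set()]; every item must satisfy
#'   `scale_min <= intended_cutoff < scale_max`.
#' @return a tibble with columns `respondent_id`, `wave`, `occupation_code`,
#'   `gender` and one column per item, carrying attributes `truth` (the
#'   per-cell generating probabilities, see [survey_truth()]), `group_map`
#'   (see [survey_group_map()]) and `scenario`.
#' @export
generate_survey <- function(scenario, item_set) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(item_set, "item_set"))
  bad <- item_set$item_id[item_set$scale_min > scenario$intended_cutoff |
                            item_set$scale_max <= scenario$intended_cutoff]
  if (length(bad)) {
    stop("intended_cutoff outside the scale of item(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gm <- scenario_group_map(scenario)
  groups <- unique(gm$jem_group_id)

  truth <- scenario$true_exposure_prob
  if (!is.null(truth)) {
    unknown <- setdiff(truth$item_id, item_set$item_id)
    if (length(unknown)) {
      stop("true_exposure_prob refers to unknown item_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  withr::with_seed(scenario$seed + 1L, {
    if (is.null(truth)) {
      truth <- tidyr::expand_grid(jem_group_id = groups,
                                  gender = .gender_levels,
                                  item_id = item_set$item_id)
      truth$prob <- runif(nrow(truth), 0.05, 0.45)
    }

    persons <- tidyr::expand_grid(jem_group_id = groups,
                                  gender = .gender_levels,
                                  wave = scenario$waves,
                                  .draw = seq_len(scenario$n_per_cell))
    # sample a code within each person's group
    codes_by_group <- split(gm$occupation_code, gm$jem_group_id)
    n_in_group <- lengths(codes_by_group)[persons$jem_group_id]
    pick <- floor(runif(nrow(persons)) * n_in_group) + 1L
    persons$occupation_code <- mapply(
      function(g, i) codes_by_group[[g]][i], persons$jem_group_id, pick,
      USE.NAMES = FALSE)
    persons$respondent_id <- sprintf("R%06d", seq_len(nrow(persons)))

    long <- tidyr::expand_grid(
      persons[c("respondent_id", "wave", "occupation_code", "gender",
                "jem_group_id")],
      item_id = item_set$item_id)
    long <- left_join(long, truth,
                      by = c("jem_group_id", "gender", "item_id"))
    if (anyNA(long$prob)) {
      stop("true_exposure_prob does not cover every (group, gender, item) cell",
           call. = FALSE)
    }
    meta <- item_set[c("item_id", "scale_min", "scale_max", "adverse_high")]
    long <- left_join(long, meta, by = "item_id")

    cut <- scenario$intended_cutoff
    n <- nrow(long)
    exposed <- rbinom(n, 1L, long$prob) == 1L
    n_hi <- long$scale_max - cut
    n_lo <- cut - long$scale_min + 1L
    aligned <- ifelse(exposed,
                      cut + floor(runif(n) * n_hi) + 1L,
                      long$scale_min + floor(runif(n) * n_lo))
    raw <- ifelse(long$adverse_high, aligned,
                  long$scale_min + long$scale_max - aligned)
    raw[runif(n) < scenario$missing_rate] <- NA_integer_

    long$value <- as.integer(raw)
    wide <- tidyr::pivot_wider(
      long[c("respondent_id", "wave", "occupation_code", "gender",
             "item_id", "value")],
      names_from = "item_id", values_from = "value")
    wide <- wide[c("respondent_id", "wave", "occupation_code", "gender",
                   item_set$item_id)]
    wide <- arrange(wide, .data$respondent_id)
    structure(wide, truth = truth, group_map = gm, scenario = scenario)
  })
}

#' Ground-truth exposure probabilities attached to a generated survey
#' @param survey output of [generate_survey()].
#' @return tibble `(jem_group_id, gender, item_id, prob)`.
#' @export
survey_truth <- function(survey) attr(survey, "truth")

#' Group map attached to a generated survey
#' @param survey output of [generate_survey()].
#' @return a [jem_group_map()].
#' @export
survey_group_map <- function(survey) attr(survey, "group_map")

#' Generate register-style microdata
#'
#' One row per person with `person_id`, `occupation_code` and `gender`. A
#' stated fraction of rows carries codes absent from the supplied list, to
#' exercise unmatched-row handling in [merge_exposures()]; the realized
#' number of planted unknown codes is attached as attribute
#' `n_unmatched_planted`.
#'
#' @param n_persons number of rows.
#' @param codes character vector of valid occupation codes.
#' @param unmatched_fraction probability a row gets a code outside `codes`.
#' @param seed integer seed.
#' @return a tibble of `n_persons` rows.
#' @export
generate_register <- function(n_persons, codes, unmatched_fraction = 0,
                              seed = 1L) {
  if (length(codes) == 0L) stop("empty code list", call. = FALSE)
  if (unmatched_fraction < 0 || unmatched_fraction > 1) {
    stop("unmatched_fraction must be in [0, 1]", call. = FALSE)
  }
  codes <- pad_code(codes)
  withr::with_seed(as.integer(seed), {
    unmatched <- runif(n_persons) < unmatched_fraction
    pool_out <- setdiff(sprintf("%04d", 0:9999), codes)
    code <- character(n_persons)
    code[!unmatched] <- sample(codes, sum(!unmatched), replace = TRUE)
    code[unmatched] <- sample(pool_out, sum(unmatched), replace = TRUE)
    out <- tibble(person_id = sprintf("P%06d", seq_len(n_persons)),
                  occupation_code = code,
                  gender = sample(.gender_levels, n_persons, replace = TRUE))
    structure(out, n_unmatched_planted = sum(unmatched))
  })
}

#' Generate a synthetic occupational-code crosswalk key
#'
#' A mostly one-to-one source-to-target mapping; a stated fraction of source
#' codes receives a second candidate target, to exercise the ambiguity
#' policies of [convert_codes()]. This is a synthetic stand-in: no official
#' correspondence key exists between the two 4-digit Norwegian occupational
#' classification versions the method targets.
#'
#' @param codes_source,codes_target non-empty character vectors of codes.
#' @param ambiguous_fraction probability a source code maps to two targets.
#' @param seed integer seed.
#' @return a [crosswalk_key()].
#' @export
generate_crosswalk <- function(codes_source, codes_target,
                               ambiguous_fraction = 0, seed = 1L) {
  if (!length(codes_source) || !length(codes_target)) {
    stop("both code lists must be non-empty", call. = FALSE)
  }
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1) {
    stop("ambiguous_fraction must be in [0, 1]", call. = FALSE)
  }
  codes_source <- unique(pad_code(codes_source))
  codes_target <- unique(pad_code(codes_target))
  withr::with_seed(as.integer(seed), {
    ns <- length(codes_source)
    primary <- if (length(codes_target) >= ns) {
      sample(codes_target, ns)
    } else {
      sample(codes_target, ns, replace = TRUE)
    }
    pairs <- tibble(source_code = codes_source, target_code = primary)
    amb <- runif(ns) < ambiguous_fraction
    if (any(amb) && length(codes_target) < 2L) {
      stop("need at least two target codes to create ambiguous mappings",
           call. = FALSE)
    }
    if (any(amb)) {
      second <- vapply(which(amb), function(i) {
        sample(setdiff(codes_target, primary[i]), 1L)
      }, character(1))
      pairs <- bind_rows(pairs, tibble(source_code = codes_source[amb],
                                       target_code = second))
    }
    crosswalk_key(pairs, provenance = sprintf(
      "synthetic key: %d sources, %d targets, ambiguous_fraction=%g, seed=%d",
      ns, length(codes_target), ambiguous_fraction, as.integer(seed)))
  })
}

#' Write a complete fixture directory
#'
#' Emits the same CSV dialects the builder consumes: `survey.csv`,
#' `register.csv`, `group_map.csv`, `crosswalk.csv` and `truth.csv`.
#'
#' @param dir output directory (created if needed).
#' @param scenario a [simulation_scenario()].
#' @param item_set an [item_set()].
#' @param n_register rows in the register table.
#' @param unmatched_fraction fraction of register rows with unknown codes.
#' @param ambiguous_fraction fraction of ambiguous crosswalk sources.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dir, scenario, item_set, n_register = 1000L,
                           unmatched_fraction = 0.1, ambiguous_fraction = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  survey <- generate_survey(scenario, item_set)
  gm <- survey_group_map(survey)
  write_survey(survey, file.path(dir, "survey.csv"))
  write_group_map(gm, file.path(dir, "group_map.csv"))
  write.csv(as.data.frame(survey_truth(survey)),
            file.path(dir, "truth.csv"), row.names = FALSE)
  reg <- generate_register(n_register, gm$occupation_code,
                           unmatched_fraction, seed = scenario$seed + 2L)
  write.csv(as.data.frame(reg), file.path(dir, "register.csv"),
            row.names = FALSE)
  # synthetic "new classification" source codes, disjoint from the targets
  src <- setdiff(sprintf("%04d", 0:9999), gm$occupation_code)
  src <- utils::head(src, length(gm$occupation_code))
  key <- generate_crosswalk(src, gm$occupation_code, ambiguous_fraction,
                            seed = scenario$seed + 3L)
  write_crosswalk(key, file.path(dir, "crosswalk.csv"))
  invisible(dir)
}
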