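## CSV readers and writers for the documented schemas, plus a YAML run
## configuration reader.  Validation errors name the offending row.

#' Write concentration-time profiles to CSV
#'
#' Columns: `subject_id, analyte, route, dose_mg_per_kg, body_weight_g,
#' time_hr, conc_ug_per_ml, blq`.
#'
#' @param profiles list of [conc_profile()] objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pk_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, analyte = p$analyte,
               route = p$route, dose_mg_per_kg = p$dose_mg_per_kg,
               body_weight_g = p$body_weight_g, time_hr = p$times_hr,
               conc_ug_per_ml = p$conc_ug_per_ml, blq = as.integer(p$blq),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read concentration-time profiles from CSV
#'
#' @param path CSV file in the [write_pk_profiles()] schema
#' @param lloq LLOQ applied to all profiles, ug/ml
#' @return list of [conc_profile()] objects
#' @export
read_pk_profiles <- function(path, lloq = 0.2) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "analyte", "route", "dose_mg_per_kg",
                "body_weight_g", "time_hr", "conc_ug_per_ml", "blq")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(bad <- !is.finite(d$time_hr))) {
    stop("non-numeric time_hr at row ", which(bad)[1])
  }
  if (any(bad <- d$blq == 0 & d$conc_ug_per_ml < 0)) {
    stop("negative quantifiable concentration at row ", which(bad)[1])
  }
  key <- interaction(d$subject_id, d$analyte, drop = TRUE)
  lapply(split(seq_len(nrow(d)), key), function(idx) {
    g <- d[idx, ]
    if (any(diff(g$time_hr) <= 0)) {
      r <- idx[which(diff(g$time_hr) <= 0)[1] + 1]
      stop("times not strictly increasing at row ", r, " (subject ",
           g$subject_id[1], ")")
    }
    conc_profile(subject_id = g$subject_id[1], analyte = g$analyte[1],
                 route = g$route[1], dose_mg_per_kg = g$dose_mg_per_kg[1],
                 body_weight_g = g$body_weight_g[1], times_hr = g$time_hr,
                 conc_ug_per_ml = g$conc_ug_per_ml, blq = g$blq == 1,
                 lloq = lloq)
  })
}

#' Write / read OGTT effect tables
#'
#' Columns: `day, dose_mg_per_kg, route, effect, se`.
#' @param data OGTT data frame
#' @param path CSV file
#' @return `path` / the data frame
#' @export
write_ogtt_data <- function(data, path) {
  utils::write.csv(data[, c("day", "dose_mg_per_kg", "route", "effect",
                            "se")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ogtt_data
#' @export
read_ogtt_data <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("day", "dose_mg_per_kg", "route", "effect")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(bad <- d$day < 0)) stop("negative day at row ", which(bad)[1])
  d
}

#' Write / read a body-weight study
#'
#' Long format with columns `arm, day, bw_g`; the vehicle series uses arm
#' label `"vehicle"`.
#'
#' @param study a [bw_study()]
#' @param path CSV file
#' @param arms arm table for reconstruction (default [standard_bw_arms()])
#' @param dosing_days,bw0 study constants for reconstruction
#' @return `path` / a [bw_study()]
#' @export
write_bw_study <- function(study, path) {
  veh <- data.frame(arm = "vehicle", day = study$vehicle$day,
                    bw_g = study$vehicle$bw_g, stringsAsFactors = FALSE)
  rows <- rbind(veh, study$treatment[, c("arm", "day", "bw_g")])
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bw_study
#' @export
read_bw_study <- function(path, arms = standard_bw_arms(),
                          dosing_days = c(0, 7, 14), bw0 = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("arm", "day", "bw_g")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  veh <- d[d$arm == "vehicle", c("day", "bw_g")]
  if (nrow(veh) == 0) stop("no vehicle rows in ", path)
  treat <- d[d$arm != "vehicle", ]
  unknown <- setdiff(unique(treat$arm), arms$label)
  if (length(unknown) > 0) {
    stop("arm(s) not in the arm table: ", paste(unknown, collapse = ", "))
  }
  if (is.null(bw0)) bw0 <- veh$bw_g[which.min(veh$day)]
  bw_study(arms = arms, dosing_days = dosing_days,
           days = sort(unique(d$day)), vehicle = veh, treatment = treat,
           bw0 = bw0)
}

#' Read a YAML run configuration
#'
#' Merges a YAML file over a list of documented defaults; unknown keys are
#' rejected with an explicit error.
#'
#' @param path YAML file
#' @param defaults named list of permitted keys with default values
#' @return merged named list
#' @export
read_run_config <- function(path, defaults) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configuration files")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}
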