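#' Map EQ-5D-5L responses to utility values
#'
#' Deterministic lookup of each response profile in a value set. Wholly
#' missing responses map to missing utilities; any level outside 1..5 is an
#' error.
#'
#' @param eq5d EQ-5D tibble from [load_eq5d()].
#' @param value_set Value-set tibble from [build_value_set()].
#' @return Tibble with `participant_id`, `week`, `utility`.
#' @export
crosswalk_utility <- function(eq5d, value_set = build_value_set()) {
  dm <- eq5d_domains()
  lv <- as.matrix(eq5d[dm])
  missing <- rowSums(is.na(lv)) == length(dm)
  ok <- lv[!missing, , drop = FALSE]
  if (length(ok) && any(ok < 1 | ok > 5 | ok != floor(ok))) {
    stop("EQ-5D levels must be integers in 1..5", call. = FALSE)
  }
  state <- rep(NA_character_, nrow(eq5d))
  state[!missing] <- apply(ok, 1, paste0, collapse = "")
  tibble::tibble(
    participant_id = eq5d$participant_id,
    week = eq5d$week,
    utility = value_set$utility[match(state, value_set$state)]
  )
}

#' Area-under-the-curve QALYs over the 28-week horizon
#'
#' Trapezoidal integration of the utility trajectory at weeks 0, 16 and 28,
#' assuming linear change between assessments, expressed in years:
#' `QALY = (u0 + u16)/2 * 16/52 + (u16 + u28)/2 * 12/52`. A participant
#' missing any of the three utilities (including those absent from the
#' table at a scheduled week) gets a missing QALY, to be handled by
#' multiple imputation downstream.
#'
#' @param utilities Tibble from [crosswalk_utility()].
#' @return Tibble with `participant_id`, `u0`, `u16`, `u28`, `qaly`.
#' @export
auc_qaly <- function(utilities) {
  wide <- utilities %>%
    dplyr::mutate(week = paste0("u", .data$week)) %>%
    tidyr::pivot_wider(id_cols = "participant_id", names_from = "week",
                       values_from = "utility")
  for (col in c("u0", "u16", "u28")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide %>%
    dplyr::mutate(qaly = trapezoid_qaly(.data$u0, .data$u16, .data$u28)) %>%
    dplyr::select("participant_id", "u0", "u16", "u28", "qaly")
}

#' Trapezoid QALY from three utilities
#'
#' Vectorised closed form for the 0/16/28-week schedule.
#' @param u0,u16,u28 Utilities at weeks 0, 16 and 28.
#' @return QALYs in years.
#' @export
trapezoid_qaly <- function(u0, u16, u28) {
  (u0 + u16) / 2 * 16 / 52 + (u16 + u28) / 2 * 12 / 52
}

#' Write the participant QALY table
#' @param qalys Output of [auc_qaly()].
#' @param path Output CSV path.
#' @export
write_qalys <- function(qalys, path) {
  readr::write_csv(qalys, path)
  invisible(path)
}
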