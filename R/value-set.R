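#' Build an EQ-5D-5L value set
#'
#' Constructs the full 3125-state lookup table mapping EQ-5D-5L response
#' profiles to a single utility index. The shipped default,
#' `"uk3l-synthetic"`, is a synthetic crosswalk-style value set: each 5L
#' domain level is placed on the 3L decrement scale by linear interpolation
#' (5L levels 1..5 correspond to 3L positions 1, 1.5, 2, 2.5, 3) and the
#' index is assembled with the additive structure used by UK 3L tariffs — a
#' constant decrement of 0.081 for any departure from full health,
#' per-domain level decrements, and an extra 0.269 decrement weighted by
#' the worst-level intensity across domains. It anchors full health
#' (1,1,1,1,1) at exactly 1 and the worst state (5,5,5,5,5) at -0.594, the
#' range of the published UK crosswalk, but its interior values are a
#' synthetic stand-in, not the published table. Value sets are pluggable:
#' any table with the same columns can be passed wherever a `value_set`
#' argument appears.
#'
#' @param id Value-set identifier. Currently `"uk3l-synthetic"`.
#' @return A tibble with 3125 rows and columns `state` (character,
#'   `"11111"`..`"55555"`), the five domain levels `mobility`, `selfcare`,
#'   `activity`, `pain`, `anxiety`, and `utility`. Attributes
#'   `value_set_id` and `min_utility` record provenance and range.
#' @examples
#' vs <- build_value_set()
#' vs$utility[vs$state == "11111"]  # exactly 1
#' min(vs$utility)
#' @export
build_value_set <- function(id = "uk3l-synthetic") {
  if (!identical(id, "uk3l-synthetic")) {
    stop("unknown value set id: ", id, call. = FALSE)
  }
  # 3L-style decrements at levels 2 and 3 per domain
  dec2 <- c(mobility = 0.069, selfcare = 0.104, activity = 0.036,
            pain = 0.123, anxiety = 0.071)
  dec3 <- c(mobility = 0.314, selfcare = 0.214, activity = 0.094,
            pain = 0.386, anxiety = 0.236)

  grid <- tidyr::expand_grid(
    mobility = 1:5, selfcare = 1:5, activity = 1:5, pain = 1:5, anxiety = 1:5
  )
  lev <- as.matrix(grid)
  # position on the 3L level scale: 1, 1.5, 2, 2.5, 3
  pos <- 1 + (lev - 1) / 2
  domains <- colnames(lev)
  dec <- matrix(0, nrow(lev), ncol(lev), dimnames = list(NULL, domains))
  for (d in domains) {
    p <- pos[, d]
    dec[, d] <- ifelse(p <= 2, (p - 1) * dec2[d],
                       dec2[d] + (p - 2) * (dec3[d] - dec2[d]))
  }
  any_dysfunction <- rowSums(lev > 1) > 0
  # worst-level term: weight 1 when a domain sits at 3L level 3 (5L level 5),
  # 0.5 at 5L level 4, 0 below; take the maximum across domains
  n3_weight <- apply(pmax(pos - 2, 0), 1, max)
  utility <- 1 - 0.081 * any_dysfunction - rowSums(dec) - 0.269 * n3_weight

  out <- grid
  out$state <- apply(lev, 1, paste0, collapse = "")
  out$utility <- round(utility, 4)
  out <- dplyr::relocate(out, "state")
  attr(out, "value_set_id") <- id
  attr(out, "min_utility") <- min(out$utility)
  out
}

#' Range of a value set
#' @param value_set A value-set tibble from [build_value_set()].
#' @return Numeric length-2 vector `c(min_utility, 1)`.
#' @export
value_set_range <- function(value_set) {
  c(min(value_set$utility), 1)
}
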