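#' Background-mortality life table
#'
#' Age-band lookup of the annual probability of death from non-stroke causes.
#' Bands must be contiguous, non-overlapping and ascending; ages beyond the
#' last band use the last band's probability (documented extrapolation), which
#' is how a 20-year horizon starting at 68 runs past the last printed band.
#'
#' @param age_start,age_end Integer-valued band limits in years (inclusive).
#' @param annual_death_prob Annual death probability per band, in `[0, 1]`.
#' @return A data frame of class `life_table`.
#' @examples
#' china_life_table()
#' @export
life_table <- function(age_start, age_end, annual_death_prob) {
  lt <- data.frame(age_start = as.numeric(age_start), age_end = as.numeric(age_end),
                   annual_death_prob = as.numeric(annual_death_prob))
  if (nrow(lt) == 0) stop("life_table: at least one band required", call. = FALSE)
  if (any(lt$age_end < lt$age_start)) stop("life_table: band end before start", call. = FALSE)
  if (any(!is.finite(lt$annual_death_prob)) ||
      any(lt$annual_death_prob < 0) || any(lt$annual_death_prob > 1)) {
    stop("life_table: annual death probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (nrow(lt) > 1) {
    gaps <- lt$age_start[-1] - lt$age_end[-nrow(lt)]
    if (any(gaps != 1)) {
      stop("life_table: bands must be contiguous and ascending (next start = previous end + 1)",
           call. = FALSE)
    }
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Look up the annual background death probability at an age
#'
#' Vectorised over `age`. Ages below the first band are an error; ages beyond
#' the last band return the last band's probability.
#'
#' @param lt A [life_table()].
#' @param age Ages in years (fractional ages fall in the band containing them).
#' @return Annual death probabilities.
#' @export
life_table_lookup <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (any(age < lt$age_start[1])) {
    stop(sprintf("life_table_lookup: age below table start (%g)", lt$age_start[1]),
         call. = FALSE)
  }
  idx <- findInterval(age, lt$age_start)
  lt$annual_death_prob[pmin(idx, nrow(lt))]
}

#' Chinese background-mortality bands
#'
#' The five published age bands for China (ages 68 through 89); later ages
#' extrapolate the last band.
#'
#' @return A [life_table()].
#' @export
china_life_table <- function() {
  life_table(age_start = c(68, 70, 75, 80, 85),
             age_end = c(69, 74, 79, 84, 89),
             annual_death_prob = c(0.01266, 0.02159, 0.03731, 0.06340, 0.15120))
}
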