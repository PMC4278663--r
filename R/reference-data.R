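# Bundled reference values from a laboratory validation session in which
# smokers each smoked six cigarettes while wearing arm-mounted inertial
# sensors. These per-participant summaries (demographics and video-coded
# smoking topography) serve as worked inputs for the summary operations
# and as realism anchors for the synthetic-session generator defaults.

#' Per-participant demographics and smoking history
#'
#' Six laboratory participants: cigarettes smoked per day, years of
#' regular smoking, Fagerstrom Test for Nicotine Dependence score (0-10)
#' and intake expired-breath carbon monoxide (ppm).
#'
#' @return data frame with columns `participant, gender, age,
#'   cigs_per_day, years_smoking, ftnd, co_ppm`.
#' @export
smoking_participants <- function() {
  data.frame(
    participant = 1:6,
    gender = c("M", "M", "M", "M", "F", "M"),
    age = c(40, 28, 28, 48, 50, 48),
    cigs_per_day = c(30, 12.5, 20, 20, 15, 20),
    years_smoking = c(28, 10, 16, 20, 30, 18),
    ftnd = c(8, 4, 3, 7, 5, 4),
    co_ppm = c(24, 10, 10, 12, 12, 14))
}

#' Per-participant video-coded smoking topography
#'
#' For the four participants who smoked naturally (no topography
#' mouthpiece), each value is averaged over their six cigarettes: puffs
#' per cigarette, mean inter-puff interval and total time spent smoking
#' one cigarette.
#'
#' @return data frame with columns `participant, puffs, interpuff_s,
#'   cigarette_time_s`.
#' @export
smoking_topography <- function() {
  data.frame(
    participant = c("1", "4", "5", "6"),
    puffs = c(8.5, 14.8, 5.8, 7.7),
    interpuff_s = c(51.1, 18.8, 56.0, 44.8),
    cigarette_time_s = c(464.0, 323.7, 325.9, 355.0))
}

#' Mean demographic and smoking-history summaries
#'
#' Cross-participant means (rounded to one decimal, half up) of the
#' numeric columns of a demographics table such as
#' [smoking_participants()].
#'
#' @param participants data frame with columns `cigs_per_day,
#'   years_smoking, ftnd, co_ppm`.
#' @return named numeric vector of the four means.
#' @export
participant_summary <- function(participants = smoking_participants()) {
  cols <- c("cigs_per_day", "years_smoking", "ftnd", "co_ppm")
  stopifnot(all(cols %in% names(participants)))
  vapply(participants[cols], function(x) round_half_up(mean(x), 1),
         numeric(1))
}
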