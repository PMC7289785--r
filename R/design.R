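# Study designs: single and multiple ascending dose cohorts with dense
# hormone sampling windows.
#
# Clock convention: time 0 = 6 a.m. of the first study day; doses are given
# at 8 a.m. (clock 2 h) and, for twice-daily regimens, 4 p.m. (clock 10 h),
# i.e. 8 h / 16 h dose intervals. The multiple-dose part runs 13 dosing
# days with hormone sampling on days 7 and 12.

DOSE_CLOCK <- 2      # first daily dose, h after 6 a.m.
LLOQ_GH <- 0.05      # ng/mL
SAMPLE_INTERVAL <- 1 / 3  # 20 min

.sad_doses <- c("0.1", "0.4", "0.8", "1.2", "1.5")
.mad_regimens <- c("1.2mg-qd", "0.8mg-bid", "1.0mg-bid")

#' Published cohort identifiers
#'
#' Five single-ascending-dose cohorts (0.1, 0.4, 0.8, 1.2, 1.5 mg), three
#' multiple-ascending-dose regimens (1.2 mg q.d., 0.8 mg b.i.d., 1.0 mg
#' b.i.d.), plus pure placebo arms sharing either sampling layout.
#'
#' @return character vector of cohort names accepted by [build_design()].
#' @export
cohort_names <- function() {
  c(paste0(.sad_doses, "mg-sad"), .mad_regimens, "placebo", "placebo-mad")
}

.normalize_cohort <- function(name) {
  x <- tolower(gsub("[ _]", "", name))
  x <- gsub("b\\.?i\\.?d\\.?", "bid", x)
  x <- gsub("q\\.?d\\.?", "qd", x)
  x <- gsub("s\\.?a\\.?d\\.?", "sad", x)
  x <- sub("^([0-9.]+)mg-?(sad|qd|bid)$", "\\1mg-\\2", x)
  if (x %in% c("placebo", "placebo-sad", "placebosad")) return("placebo")
  if (x %in% c("placebomad", "placebo-mad")) return("placebo-mad")
  x
}

.sampling_times <- function(day, part) {
  # Returns clock-normalised times (h since 6 a.m. day 1) for one occasion.
  dose_t <- DOSE_CLOCK + 24 * (day - 1)
  if (part == "sad") {
    # -2 h to +12 h at 20-min grid, except 15/30/60 min replace the first hour
    grid <- seq(-2, 12, by = SAMPLE_INTERVAL)
    grid <- grid[!(grid > 0 & grid < 1 + 1e-9)]
    grid <- sort(c(grid, 0.25, 0.5, 1.0))
  } else {
    grid <- seq(-1, 11, by = SAMPLE_INTERVAL)
  }
  dose_t + grid
}

#' Build a published trial design
#'
#' Returns the dosing events and hormone sampling schedule of one cohort of
#' the phase-1 single/multiple ascending dose study: subcutaneous doses of
#' 0.1--1.5 mg (single), 1.2 mg once daily or 0.8/1.0 mg twice daily at
#' 8 h/16 h intervals over 13 days; 20-min hormone sampling from -2 h to
#' +12 h around the single dose (with 15/30/60-min points in the first
#' hour) or from -1 h to +11 h around the morning dose on days 7 and 12.
#'
#' @param name cohort identifier, e.g. `"1.5mg-sad"`, `"1.0 mg b.i.d."`,
#'   `"1.2mg-qd"`, `"placebo"` (single-dose sampling layout) or
#'   `"placebo-mad"` (day 7/12 layout). Case, spaces and dots are ignored.
#' @return an object of class `study_design`: list with `name`, `part`
#'   (`"sad"`/`"mad"`), `doses` (data.frame `time`, `amt` in mg),
#'   `occasions` (data.frame `occ`, `day`, `dose_time`) and `sampling`
#'   (list of clock-normalised sampling time vectors per occasion).
#' @examples
#' d <- build_design("1.0mg-bid")
#' head(d$doses)
#' @export
build_design <- function(name) {
  key <- .normalize_cohort(name)
  valid <- c(paste0(.sad_doses, "mg-sad"), .mad_regimens,
             "placebo", "placebo-mad")
  if (!key %in% valid) {
    stop("unknown cohort '", name, "'; expected one of: ",
         paste(valid, collapse = ", "))
  }
  if (key %in% c(paste0(.sad_doses, "mg-sad"), "placebo")) {
    part <- "sad"
    amt <- if (key == "placebo") numeric(0) else
      as.numeric(sub("mg-sad", "", key))
    doses <- if (length(amt)) data.frame(time = DOSE_CLOCK, amt = amt) else
      data.frame(time = numeric(0), amt = numeric(0))
    days <- 1
  } else {
    part <- "mad"
    n_days <- 13
    if (key == "1.2mg-qd") {
      dose_times <- DOSE_CLOCK + 24 * (seq_len(n_days) - 1)
      amt <- rep(1.2, n_days)
    } else if (key %in% c("0.8mg-bid", "1.0mg-bid")) {
      per <- if (key == "0.8mg-bid") 0.8 else 1.0
      morning <- DOSE_CLOCK + 24 * (seq_len(n_days) - 1)
      dose_times <- sort(c(morning, morning + 8))  # 8 h then 16 h interval
      amt <- rep(per, length(dose_times))
    } else { # placebo-mad
      dose_times <- numeric(0)
      amt <- numeric(0)
    }
    doses <- data.frame(time = dose_times, amt = amt)
    days <- c(7, 12)
  }
  if (nrow(doses) && any(diff(doses$time) <= 0)) {
    stop("dose times must be strictly increasing")
  }
  occasions <- data.frame(
    occ = match(days, c(1, 7, 12)),
    day = days,
    dose_time = DOSE_CLOCK + 24 * (days - 1)
  )
  sampling <- lapply(days, .sampling_times, part = part)
  structure(
    list(name = key, part = part, doses = doses,
         occasions = occasions, sampling = sampling),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$name, sprintf("(%s part)\n", toupper(x$part)))
  cat("  doses:", if (nrow(x$doses)) paste0(nrow(x$doses), " x ",
      unique(x$doses$amt), " mg") else "none (placebo)", "\n")
  cat("  sampling occasions (day):", paste(x$occasions$day, collapse = ", "),
      "\n")
  invisible(x)
}
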