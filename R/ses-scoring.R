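#' Overcrowding index
#'
#' Ratio between the number of rooms available in the house and the number of
#' persons living in the household. Lower values indicate worse crowding.
#'
#' @param rooms Nonnegative room count.
#' @param persons Household size, at least 1.
#' @return `rooms / persons`, vectorized.
#' @examples
#' overcrowding_index(3, 4) # 0.75
#' @export
overcrowding_index <- function(rooms, persons) {
  assert_that(all(persons >= 1, na.rm = TRUE),
              "persons must be >= 1 to compute an overcrowding index")
  assert_that(all(rooms >= 0, na.rm = TRUE), "rooms must be nonnegative")
  rooms / persons
}

childhood_tenure_levels <- function() c("rented", "one_dwelling", "multi_dwelling")
education_levels <- function() c("primary", "lower_secondary", "upper_secondary", "post_secondary")
occupation_levels <- function() {
  c("professional_managerial", "skilled_non_manual", "skilled_manual",
    "partly_unskilled_unclassified")
}

check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
  if (length(bad))
    stop(sprintf("unknown %s value(s): %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

#' Score childhood socioeconomic position (age 8)
#'
#' Three indicators each coded 0-1: housing tenure (0 if rented, 1 for any
#' dwelling ownership), access to hot water (1 if present), and an
#' overcrowding point (1 if rooms/persons is at or above the population median
#' cutoff, default 0.6). The combined 0-3 score is dichotomized as low (< 2)
#' versus high (>= 2).
#'
#' @param tenure One of `"rented"`, `"one_dwelling"`, `"multi_dwelling"`.
#' @param hot_water Logical, access to hot water.
#' @param rooms,persons Household rooms and size at age 8.
#' @param crowding_cutoff Overcrowding ratio earning the point; default 0.6.
#' @return A data.frame with the three points, `total` (0-3) and `class`
#'   (`"low"`/`"high"`), one row per input.
#' @examples
#' score_childhood("one_dwelling", TRUE, 3, 4) # total 3, high
#' @export
score_childhood <- function(tenure, hot_water, rooms, persons,
                            crowding_cutoff = 0.6) {
  check_levels(tenure, childhood_tenure_levels(), "childhood housing tenure")
  tenure_point <- ifelse(tenure == "rented", 0L, 1L)
  hot_water_point <- as.integer(as.logical(hot_water))
  crowding_point <- as.integer(overcrowding_index(rooms, persons) >= crowding_cutoff)
  total <- tenure_point + hot_water_point + crowding_point
  data.frame(tenure_point = tenure_point, hot_water_point = hot_water_point,
             crowding_point = crowding_point, total = total,
             class = ifelse(total < 2, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Dichotomize educational attainment
#'
#' Up to lower secondary school is low; upper secondary school or higher is
#' high.
#'
#' @param level One of `"primary"`, `"lower_secondary"`, `"upper_secondary"`,
#'   `"post_secondary"`.
#' @return `"low"` or `"high"`, vectorized.
#' @export
score_education <- function(level) {
  check_levels(level, education_levels(), "education level")
  ifelse(level %in% c("primary", "lower_secondary"), "low", "high")
}

#' Score adult material socioeconomic position
#'
#' A six-point scale: housing tenure (0/1/2 points for rented, one dwelling,
#' more than one dwelling), occupational social class (3/2/1/0 points for
#' professional-managerial, skilled non-manual, skilled manual, partly
#' skilled/unskilled/unclassified), and an overcrowding point (0 when
#' rooms/persons is below the population median of 1, else 1). Total 0-6,
#' dichotomized as low (<= 3) versus high (> 3).
#'
#' @param tenure Housing tenure, same levels as childhood.
#' @param occupation One of the four occupational class levels.
#' @param rooms,persons Adult household rooms and size.
#' @param crowding_cutoff Ratio below which the crowding point is 0; default 1.
#' @return A data.frame with the points, `total` (0-6) and `class`.
#' @examples
#' score_adult("one_dwelling", "skilled_non_manual", 4, 4) # total 4, high
#' @export
score_adult <- function(tenure, occupation, rooms, persons,
                        crowding_cutoff = 1) {
  check_levels(tenure, childhood_tenure_levels(), "adult housing tenure")
  check_levels(occupation, occupation_levels(), "occupational class")
  tenure_points <- match(tenure, childhood_tenure_levels()) - 1L
  occupation_points <- 4L - match(occupation, occupation_levels())
  crowding_point <- as.integer(overcrowding_index(rooms, persons) >= crowding_cutoff)
  total <- tenure_points + occupation_points + crowding_point
  data.frame(tenure_points = tenure_points,
             occupation_points = occupation_points,
             crowding_point = crowding_point, total = total,
             class = ifelse(total <= 3, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Classify the life-course socioeconomic trajectory
#'
#' Maps the (childhood, education, adult) low/high triple to one of eight
#' labels, anchored at `stable_high` = high/high/high and `stable_low` =
#' low/low/low; the intermediate names describe which components drop or rise
#' relative to the life-course start.
#'
#' @param childhood,education,adult `"low"` or `"high"` (or `"L"`/`"H"`).
#' @return Trajectory label(s) from [trajectory_levels()], vectorized.
#' @examples
#' classify_trajectory("high", "low", "low") # education_and_material_downward
#' @export
classify_trajectory <- function(childhood, education, adult) {
  norm <- function(x, what) {
    x <- as.character(x)
    x[x == "L"] <- "low"; x[x == "H"] <- "high"
    if (anyNA(x)) stop(sprintf("missing %s class: score all three stages (impute upstream) before classifying", what), call. = FALSE)
    check_levels(x, c("low", "high"), what)
    x
  }
  childhood <- norm(childhood, "childhood class")
  education <- norm(education, "education class")
  adult <- norm(adult, "adult class")
  key <- paste(childhood, education, adult, sep = "|")
  map <- c("high|high|high" = "stable_high",
           "high|low|high"  = "education_downward",
           "high|high|low"  = "material_downward",
           "high|low|low"   = "education_and_material_downward",
           "low|high|high"  = "education_and_material_upward",
           "low|low|high"   = "material_upward",
           "low|high|low"   = "education_upward",
           "low|low|low"    = "stable_low")
  unname(map[key])
}

#' Score SES indicators of a cohort table into trajectories
#'
#' Applies [score_childhood()], [score_education()] and [score_adult()] to the
#' indicator columns of a cohort table and appends `childhood_class`,
#' `education_class`, `adult_class` and the 8-level `trajectory` factor
#' (reference `stable_high`).
#'
#' @param table A cohort data.frame with the SES indicator columns produced by
#'   [generate_cohort()] (or equivalently named real data).
#' @param crowding_cutoff_childhood,crowding_cutoff_adult Median cutoffs for
#'   the two overcrowding points; fixed population constants by default.
#' @param reestimate_cutoffs If `TRUE`, re-estimate both cutoffs as the sample
#'   medians of the respective overcrowding indices.
#' @return The table with the four scoring columns appended.
#' @export
score_ses <- function(table, crowding_cutoff_childhood = 0.6,
                      crowding_cutoff_adult = 1,
                      reestimate_cutoffs = FALSE) {
  need <- c("housing_tenure_childhood", "hot_water", "rooms_childhood",
            "persons_childhood", "education_level", "housing_tenure_adult",
            "occupational_class", "rooms_adult", "persons_adult")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks SES indicator column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (reestimate_cutoffs) {
    crowding_cutoff_childhood <- stats::median(
      overcrowding_index(table$rooms_childhood, table$persons_childhood), na.rm = TRUE)
    crowding_cutoff_adult <- stats::median(
      overcrowding_index(table$rooms_adult, table$persons_adult), na.rm = TRUE)
  }
  ch <- score_childhood(table$housing_tenure_childhood, table$hot_water,
                        table$rooms_childhood, table$persons_childhood,
                        crowding_cutoff = crowding_cutoff_childhood)
  ad <- score_adult(table$housing_tenure_adult, table$occupational_class,
                    table$rooms_adult, table$persons_adult,
                    crowding_cutoff = crowding_cutoff_adult)
  table$childhood_class <- ch$class
  table$education_class <- score_education(table$education_level)
  table$adult_class <- ad$class
  table$trajectory <- factor(
    classify_trajectory(table$childhood_class, table$education_class,
                        table$adult_class),
    levels = trajectory_levels())
  table
}
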