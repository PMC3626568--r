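#' Condition specification for a plate design
#'
#' @param condition_id Short unique label, e.g. `"N0.2"`.
#' @param nutrient `"nitrogen"` or `"glucose"` (which nutrient is titrated).
#' @param s0 Initial limiting-substrate concentration (mM).
#' @param strain `"wildtype"`, `"mutant_no_pulse"` or `"nonlimiting"`
#'   (the last marks a condition whose growth stop is density-driven).
#' @param reporter Reporter name (e.g. `"glnA"`) or `"none"`.
#' @return A list of class `plate_condition`.
#' @export
plate_condition <- function(condition_id, nutrient = c("nitrogen", "glucose"),
                            s0, strain = c("wildtype", "mutant_no_pulse",
                                           "nonlimiting"),
                            reporter = "none") {
  nutrient <- match.arg(nutrient)
  strain <- match.arg(strain)
  stopifnot(is.character(condition_id), length(condition_id) == 1L,
            is.numeric(s0), length(s0) == 1L, s0 >= 0)
  structure(list(condition_id = condition_id, nutrient = nutrient, s0 = s0,
                 strain = strain, reporter = reporter),
            class = "plate_condition")
}

all_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
}

#' Two-condition checkerboard plate design
#'
#' Assigns two conditions to the 96 wells of a plate in a checkerboard
#' pattern: no two orthogonal neighbours share a condition, and each
#' condition occupies exactly 48 wells. The alternating layout cancels
#' spatial plate effects (edge/gradient artifacts) between the conditions.
#'
#' @param cond_a,cond_b Two distinct [plate_condition()] specifications.
#' @param plate_id Plate label.
#' @return A list of class `plate_design` with elements `plate_id`, `wells`
#'   (data.frame well -> condition_id) and `conditions` (named list).
#' @export
make_checkerboard_design <- function(cond_a, cond_b, plate_id = "plate1") {
  stopifnot(inherits(cond_a, "plate_condition"),
            inherits(cond_b, "plate_condition"))
  if (identical(cond_a$condition_id, cond_b$condition_id)) {
    stop("make_checkerboard_design: the two conditions must be distinct")
  }
  wells <- all_wells()
  row_i <- match(substr(wells, 1, 1), LETTERS)
  col_i <- as.integer(substring(wells, 2))
  pick_a <- (row_i + col_i) %% 2L == 0L
  design <- list(
    plate_id = plate_id,
    wells = data.frame(
      well = wells,
      condition_id = ifelse(pick_a, cond_a$condition_id, cond_b$condition_id),
      stringsAsFactors = FALSE),
    conditions = stats::setNames(list(cond_a, cond_b),
                                 c(cond_a$condition_id, cond_b$condition_id)))
  class(design) <- "plate_design"
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "plate_design"))
  if (nrow(design$wells) > 96L) stop("plate_design: more than 96 wells")
  missing <- setdiff(design$wells$condition_id, names(design$conditions))
  if (length(missing)) {
    stop("plate_design: wells reference unknown condition(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(design)
}

well_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * i
}

#' Generate a noisy synthetic plate dataset
#'
#' Emulates the robotic plate-reader assay: for every well the deterministic
#' trajectory of its condition is sampled on the OD grid (every `od_period`
#' min) and, for reporter conditions, on the GFP grid (every `gfp_period`
#' min), then perturbed multiplicatively as
#' `value = day_factor * well_factor * truth(t) * read_noise`.
#' The day factor is drawn once per plate, the well factor once per well, the
#' read noise independently per read; all are mean-1 lognormal with the CVs in
#' `noise`. Each well consumes its own seeded random stream, so adding wells
#' does not perturb the draws of existing wells.
#'
#' @param design A [make_checkerboard_design()] plate design.
#' @param params_by_condition Named list (by condition_id), each element a
#'   list with components `sim` ([sim_params()]) and optionally `promoter`
#'   ([promoter_params()]).
#' @param noise A [noise_params()] object (its `seed` drives all draws).
#' @param od_period OD sampling period (min), default 3.
#' @param gfp_period GFP sampling period (min), default 8.
#' @return A list of class `plate_dataset` with elements `design`, `records`
#'   (long data.frame: plate_id, well, time_min, channel, value) and `meta`.
#' @export
generate_plate <- function(design, params_by_condition, noise,
                           od_period = 3, gfp_period = 8) {
  validate_design(design)
  stopifnot(inherits(noise, "noise_params"))
  cond_ids <- unique(design$wells$condition_id)
  absent <- setdiff(cond_ids, names(params_by_condition))
  if (length(absent)) {
    stop("generate_plate: no parameters for condition(s): ",
         paste(absent, collapse = ", "))
  }

  t_end <- min(vapply(params_by_condition[cond_ids],
                      function(p) p$sim$t_end, numeric(1)))
  od_grid <- seq(0, t_end, by = od_period)
  gfp_grid <- seq(0, t_end, by = gfp_period)

  truth <- lapply(cond_ids, function(cid) {
    pc <- params_by_condition[[cid]]
    has_gfp <- !is.null(pc$promoter) &&
      !identical(design$conditions[[cid]]$reporter, "none")
    grid <- sort(unique(c(od_grid, if (has_gfp) gfp_grid)))
    tr <- simulate_batch(pc$sim, promoter = pc$promoter, grid = grid)
    list(od = stats::approx(tr$time, tr$od, od_grid)$y,
         gfp = if (has_gfp) stats::approx(tr$time, tr$gfp, gfp_grid)$y,
         has_gfp = has_gfp)
  })
  names(truth) <- cond_ids

  set.seed(noise$seed)
  day_factor <- rlnorm_cv(1L, noise$day_scale_cv)

  recs <- vector("list", nrow(design$wells))
  for (i in seq_len(nrow(design$wells))) {
    w <- design$wells$well[i]
    cid <- design$wells$condition_id[i]
    tr <- truth[[cid]]
    set.seed(well_seed(noise$seed, i))
    wf <- rlnorm_cv(1L, noise$well_scale_cv)
    od_vals <- day_factor * wf * tr$od *
      rlnorm_cv(length(od_grid), noise$read_cv)
    rec <- data.frame(plate_id = design$plate_id, well = w,
                      time_min = od_grid, channel = "OD600",
                      value = od_vals, stringsAsFactors = FALSE)
    if (tr$has_gfp) {
      gfp_vals <- day_factor * wf * tr$gfp *
        rlnorm_cv(length(gfp_grid), noise$gfp_read_cv)
      rec <- rbind(rec, data.frame(plate_id = design$plate_id, well = w,
                                   time_min = gfp_grid, channel = "GFP535",
                                   value = gfp_vals, stringsAsFactors = FALSE))
    }
    recs[[i]] <- rec
  }

  structure(list(design = design,
                 records = do.call(rbind, recs),
                 meta = list(noise = noise, od_period = od_period,
                             gfp_period = gfp_period,
                             day_factor = day_factor)),
            class = "plate_dataset")
}

#' Write / read a plate dataset as long-format CSV
#'
#' `write_plate()` writes the measurement table as delimited text with header
#' `plate_id, well, time_min, channel, value` (numbers at full precision) and
#' a sidecar design table (`<path minus .csv>_design.csv` with columns
#' `well, condition_id, nutrient, s0_mM, strain, reporter`). `read_plate()`
#' reads both back and validates the records: known channels, positive
#' values, strictly increasing times per well and channel; malformed rows are
#' rejected with their row index. Missing wells are accepted (downstream
#' averaging uses the number of wells actually present). Generation metadata
#' is not persisted; the round trip preserves `records` and `design`.
#'
#' @param dataset A `plate_dataset`.
#' @param path Path of the records CSV.
#' @return `write_plate()` returns `path` invisibly; `read_plate()` returns a
#'   `plate_dataset`.
#' @export
write_plate <- function(dataset, path) {
  stopifnot(inherits(dataset, "plate_dataset"))
  rec <- dataset$records
  rec$time_min <- sprintf("%.17g", rec$time_min)
  rec$value <- sprintf("%.17g", rec$value)
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  dtab <- design_table(dataset$design)
  utils::write.csv(dtab, design_path(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

design_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_design.csv")
}

design_table <- function(design) {
  conds <- design$conditions[design$wells$condition_id]
  data.frame(well = design$wells$well,
             condition_id = design$wells$condition_id,
             nutrient = vapply(conds, `[[`, "", "nutrient"),
             s0_mM = vapply(conds, `[[`, 0, "s0"),
             strain = vapply(conds, `[[`, "", "strain"),
             reporter = vapply(conds, `[[`, "", "reporter"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(plate_id = "character",
                                        well = "character",
                                        time_min = "numeric",
                                        channel = "character",
                                        value = "numeric"))
  bad_chan <- which(!rec$channel %in% c("OD600", "GFP535"))
  if (length(bad_chan)) {
    stop("read_plate: unknown channel at row ", bad_chan[1L], ": '",
         rec$channel[bad_chan[1L]], "'")
  }
  bad_val <- which(!is.finite(rec$value) | rec$value < 0)
  if (length(bad_val)) {
    stop("read_plate: negative or non-numeric value at row ", bad_val[1L])
  }
  for (key in split(seq_len(nrow(rec)),
                    paste(rec$well, rec$channel, sep = "/"))) {
    tt <- rec$time_min[key]
    if (is.unsorted(tt, strictly = TRUE)) {
      stop("read_plate: non-monotone times for well ", rec$well[key[1L]],
           " channel ", rec$channel[key[1L]], " near row ",
           key[which(diff(tt) <= 0)[1L] + 1L])
    }
  }
  dtab <- utils::read.csv(design_path(path), stringsAsFactors = FALSE)
  conds <- lapply(split(dtab, dtab$condition_id), function(d) {
    plate_condition(d$condition_id[1L], d$nutrient[1L], d$s0_mM[1L],
                    d$strain[1L], d$reporter[1L])
  })
  design <- structure(list(plate_id = rec$plate_id[1L],
                           wells = dtab[, c("well", "condition_id")],
                           conditions = conds),
                      class = "plate_design")
  validate_design(design)
  structure(list(design = design, records = rec, meta = list()),
            class = "plate_dataset")
}
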