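#' Build a nested half-sib breeding design
#'
#' Generates the block -> sire -> dam -> offspring hierarchy of a nested
#' paternal half-sib, maternal full-sib breeding design in which each dam's
#' offspring are split between a high- and a low-density rearing treatment.
#' Sires are nested in temporal mating blocks and dams are nested in sires.
#'
#' `sires_per_block` and `dams_per_sire` may be given either as an explicit
#' per-unit vector (length `n_blocks`, resp. total number of sires) or as a
#' `(min, max)` range.  A range is sampled uniformly and then adjusted,
#' within its bounds, so that the totals match `total_sires` /
#' `total_dams` when those are supplied.
#'
#' @param n_blocks number of temporal mating blocks.
#' @param sires_per_block explicit per-block sire counts (length
#'   `n_blocks`), a single count, or a `(min, max)` range.
#' @param dams_per_sire explicit per-sire dam counts, a single count, or a
#'   `(min, max)` range.
#' @param offspring_per_dam_per_treatment number of offspring tested per dam
#'   in each density treatment (default 6, i.e. 12 per dam).
#' @param females_per_treatment number of those offspring that are female
#'   (default: half, with any odd remainder assigned a random sex).
#' @param total_sires,total_dams optional totals enforced when the
#'   corresponding count argument is a range.
#' @param attrition independent per-offspring dropout probability emulating
#'   rearing mortality (default 0).
#' @param seed RNG seed; the design is deterministic given the seed.
#'
#' @return An object of class `breeding_design`: a list with data frames
#'   `blocks` (block), `sires` (sire, block), `dams` (dam, sire) and
#'   `offspring` (individual, dam, treatment, sex).
#'
#' @examples
#' d <- build_pedigree(n_blocks = 2, sires_per_block = 2, dams_per_sire = 2,
#'                     offspring_per_dam_per_treatment = 3, seed = 1)
#' summary(d)
#' @seealso [cricket_design()] for the study-scale default configuration.
#' @export
build_pedigree <- function(n_blocks = 7,
                           sires_per_block = c(2, 2, 3, 3, 3, 4, 6),
                           dams_per_sire = c(2, 3),
                           offspring_per_dam_per_treatment = 6,
                           females_per_treatment = NULL,
                           total_sires = NULL,
                           total_dams = 59,
                           attrition = 0,
                           seed = 1) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  offs <- check_count(offspring_per_dam_per_treatment,
                      "offspring_per_dam_per_treatment")
  if (length(offs) != 1L) {
    stop("`offspring_per_dam_per_treatment` must be a single count",
         call. = FALSE)
  }
  if (!is.null(females_per_treatment)) {
    females_per_treatment <- check_count(females_per_treatment,
                                         "females_per_treatment", min = 0L)
    if (females_per_treatment > offs) {
      stop("`females_per_treatment` cannot exceed offspring per treatment",
           call. = FALSE)
    }
  }
  if (!is.numeric(attrition) || length(attrition) != 1L ||
      attrition < 0 || attrition >= 1) {
    stop("`attrition` must be a probability in [0, 1)", call. = FALSE)
  }
  check_seed(seed)

  with_seed(seed, {
    n_sires_by_block <- resolve_counts(sires_per_block, n_blocks,
                                       total = total_sires,
                                       name = "sires_per_block")
    n_sires <- sum(n_sires_by_block)
    n_dams_by_sire <- resolve_counts(dams_per_sire, n_sires,
                                     total = total_dams,
                                     name = "dams_per_sire")
    n_dams <- sum(n_dams_by_sire)

    blocks <- data.frame(block = sprintf("B%d", seq_len(n_blocks)))
    sires <- data.frame(
      sire = sprintf("S%02d", seq_len(n_sires)),
      block = rep(blocks$block, times = n_sires_by_block)
    )
    dams <- data.frame(
      dam = sprintf("D%02d", seq_len(n_dams)),
      sire = rep(sires$sire, times = n_dams_by_sire)
    )

    per_trt <- offs
    n_off_planned <- n_dams * 2L * per_trt
    off_dam <- rep(dams$dam, each = 2L * per_trt)
    off_trt <- rep(rep(c("high", "low"), each = per_trt), times = n_dams)
    off_sex <- unlist(lapply(seq_len(n_dams * 2L), function(i) {
      assign_sexes(per_trt, females_per_treatment)
    }), use.names = FALSE)
    keep <- if (attrition > 0) {
      runif(n_off_planned) >= attrition
    } else {
      rep(TRUE, n_off_planned)
    }
    offspring <- data.frame(
      individual = sprintf("I%04d", seq_len(sum(keep))),
      dam = off_dam[keep],
      treatment = factor(off_trt[keep], levels = c("high", "low")),
      sex = factor(off_sex[keep], levels = c("F", "M"))
    )

    design <- structure(
      list(blocks = blocks, sires = sires, dams = dams,
           offspring = offspring,
           settings = list(seed = seed, attrition = attrition,
                           offspring_per_dam_per_treatment = per_trt)),
      class = "breeding_design"
    )
    validate_design(design)
    design
  })
}

# Resolve an explicit-vector / scalar / (min, max)-range count specification
# into a per-unit integer vector summing to `total` when given.
resolve_counts <- function(x, n_units, total = NULL, name = "counts") {
  x <- check_count(x, name)
  is_range <- FALSE
  if (length(x) == 1L) {
    counts <- rep(x, n_units)
  } else if (length(x) == n_units) {
    counts <- x
  } else if (length(x) == 2L && x[1] <= x[2]) {
    counts <- sample(seq(x[1], x[2]), n_units, replace = TRUE)
    is_range <- TRUE
  } else {
    stop(sprintf("`%s` must be a single count, a (min, max) range, or one count per unit (%d)",
                 name, n_units), call. = FALSE)
  }
  lo <- min(x); hi <- max(x)
  # a total cap only constrains a sampled range; explicit counts stand as-is
  if (is_range && !is.null(total)) {
    total <- check_count(total, paste0("total for ", name))
    if (total < n_units * lo || total > n_units * hi) {
      stop(sprintf("total %d for `%s` is unreachable with counts in [%d, %d]",
                   total, name, lo, hi), call. = FALSE)
    }
    while (sum(counts) != total) {
      if (sum(counts) < total) {
        i <- sample(which(counts < hi), 1L)
        counts[i] <- counts[i] + 1L
      } else {
        i <- sample(which(counts > lo), 1L)
        counts[i] <- counts[i] - 1L
      }
    }
  }
  counts
}

# Sexes of the offspring tested for one dam x treatment cell.  Defaults to an
# even split, assigning any odd remainder at random.
assign_sexes <- function(n, n_female = NULL) {
  if (is.null(n_female)) {
    n_female <- n %/% 2L + rbinom(1L, 1L, (n %% 2L) / 2)
  }
  sample(rep(c("F", "M"), times = c(n_female, n - n_female)))
}

#' Study-scale breeding design
#'
#' Convenience wrapper around [build_pedigree()] with the scale of the
#' cricket density experiment the package models: 7 temporal blocks holding
#' 23 sires (median 3 per block, range 2-6), 59 dams nested in sires, and 12
#' planned offspring per dam (6 per density treatment, 3 of each sex) with a
#' rearing-attrition probability calibrated so that about 679 of the 708
#' planned offspring survive to testing.
#'
#' @param seed RNG seed.
#' @param attrition per-offspring dropout probability (default `29/708`).
#' @return A `breeding_design`.
#' @export
cricket_design <- function(seed = 1, attrition = 29 / 708) {
  build_pedigree(seed = seed, attrition = attrition)
}

validate_design <- function(design) {
  stopifnot(inherits(design, "breeding_design"))
  with(design, {
    if (anyDuplicated(blocks$block) || anyDuplicated(sires$sire) ||
        anyDuplicated(dams$dam) || anyDuplicated(offspring$individual)) {
      stop("design ids must be unique within each level", call. = FALSE)
    }
    if (!all(sires$block %in% blocks$block)) {
      stop("every sire must map to a known block", call. = FALSE)
    }
    if (!all(dams$sire %in% sires$sire)) {
      stop("every dam must map to a known sire", call. = FALSE)
    }
    if (!all(offspring$dam %in% dams$dam)) {
      stop("every offspring must map to a known dam", call. = FALSE)
    }
    if (!all(levels(offspring$treatment) == c("high", "low")) ||
        !all(levels(offspring$sex) == c("F", "M"))) {
      stop("treatment/sex must be the binary labels high/low and F/M",
           call. = FALSE)
    }
  })
  invisible(design)
}

#' Flatten a breeding design into a per-individual pedigree table
#'
#' @param x a `breeding_design`.
#' @param row.names,optional,... ignored; present for the S3 generic.
#' @return A data frame with one row per offspring and columns `individual`,
#'   `dam`, `sire`, `block`, `treatment`, `sex`.
#' @export
as.data.frame.breeding_design <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  tab <- merge(x$offspring, x$dams, by = "dam", sort = FALSE)
  tab <- merge(tab, x$sires, by = "sire", sort = FALSE)
  tab <- tab[order(tab$individual),
             c("individual", "dam", "sire", "block", "treatment", "sex")]
  rownames(tab) <- NULL
  tab
}

#' @export
print.breeding_design <- function(x, ...) {
  cat("Nested half-sib breeding design\n")
  cat(sprintf("  %d blocks, %d sires, %d dams, %d offspring\n",
              nrow(x$blocks), nrow(x$sires), nrow(x$dams),
              nrow(x$offspring)))
  trt <- table(x$offspring$treatment)
  sx <- table(x$offspring$sex)
  cat(sprintf("  treatment: %d high / %d low;  sex: %d F / %d M\n",
              trt[["high"]], trt[["low"]], sx[["F"]], sx[["M"]]))
  invisible(x)
}

#' @export
summary.breeding_design <- function(object, ...) {
  spb <- table(object$sires$block)
  dps <- table(object$dams$sire)
  out <- list(
    n_blocks = nrow(object$blocks),
    n_sires = nrow(object$sires),
    n_dams = nrow(object$dams),
    n_offspring = nrow(object$offspring),
    sires_per_block = as.integer(spb),
    dams_per_sire = as.integer(dps)
  )
  cat(sprintf(
    "%d blocks | %d sires (median %s/block, range %d-%d) | %d dams | %d offspring\n",
    out$n_blocks, out$n_sires, format(stats::median(out$sires_per_block)),
    min(out$sires_per_block), max(out$sires_per_block),
    out$n_dams, out$n_offspring))
  invisible(out)
}
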