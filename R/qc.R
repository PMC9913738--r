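# Reproducibility and linearity QC ----------------------------------------

#' Reproducibility (CV%) filter
#'
#' Coefficient of variation per species over replicates, CV% = SD/mean x
#' 100 with the sample SD (n-1 denominator). Species at or below
#' `cv_limit` are eligible; the platform's eligibility limit is CV% <= 30,
#' with CV% <= 20 counting as good-to-excellent reproducibility.
#'
#' @param mat numeric matrix, species x replicates (rownames = species).
#' @param cv_limit eligibility limit in percent (default 30).
#' @return a `qc_report` data.frame with per-species `mean`, `sd`, `sem`,
#'   `cv`, `eligible` and attributes `n_eligible`, `frac_cv20` (fraction of
#'   eligible species with CV% <= 20), `cv_limit`.
#' @export
cv_filter <- function(mat, cv_limit = 30) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 replicates per species")
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  cv <- ifelse(m > 0, s / m * 100, NA_real_)
  out <- data.frame(species = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                    mean = m, sd = s, sem = s / sqrt(ncol(mat)),
                    cv = cv,
                    eligible = !is.na(cv) & cv <= cv_limit,
                    row.names = NULL)
  elig <- out$cv[out$eligible]
  structure(out,
            n_eligible = sum(out$eligible),
            frac_cv20 = if (length(elig)) mean(elig <= 20) else NA_real_,
            cv_limit = cv_limit,
            class = c("qc_report", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", nrow(x), " species, ", attr(x, "n_eligible"),
      " eligible at CV% <= ", attr(x, "cv_limit"),
      sprintf(" (%.0f%% of eligible at CV%% <= 20)\n",
              100 * attr(x, "frac_cv20")), sep = "")
  invisible(x)
}

#' Linearity-of-quantification regression over an area series
#'
#' Ordinary least squares of amount versus dissected area over all
#' replicate points (intercept included), per species and for the membrane
#' total. Eligibility follows the platform's criterion R^2 > 0.7. Also
#' counts quantifiable species per area level: a species counts at a level
#' when its amount is positive in at least half of the replicates there.
#'
#' @param amounts long data.frame with columns `area`, `replicate`,
#'   `species`, `pmol` (absent species may be missing or zero).
#' @param membrane_species optional character vector; when given, the
#'   membrane total per (area, replicate) is the sum over these species,
#'   otherwise over all species.
#' @param r2_eligible eligibility threshold (default 0.7).
#' @return a `linearity_report`: data.frame of per-species `slope`,
#'   `intercept`, `r_squared`, `eligible`, with attributes
#'   `membrane_fit` (list: slope, intercept, r_squared) and
#'   `quantifiable_counts` (data.frame area, n_species).
#' @export
linearity_fit <- function(amounts, membrane_species = NULL,
                          r2_eligible = 0.7) {
  stopifnot(all(c("area", "replicate", "species", "pmol") %in% names(amounts)))
  if (length(unique(amounts$area)) < 3L)
    stop("need >= 3 distinct area levels")
  # complete the grid: unobserved (area, replicate, species) are zeros
  samples <- unique(amounts[c("area", "replicate")])
  species <- unique(amounts$species)
  full <- merge(merge(samples, data.frame(species = species)), amounts,
                all.x = TRUE)
  full$pmol[is.na(full$pmol)] <- 0
  fit1 <- function(x, y) {
    f <- stats::lm(y ~ x)
    sst <- sum((y - mean(y))^2)
    # computed directly so exact proportional series give R^2 = 1 cleanly
    r2 <- if (sst > 0) 1 - sum(stats::residuals(f)^2) / sst else 1
    c(slope = unname(stats::coef(f)[2]), intercept = unname(stats::coef(f)[1]),
      r_squared = r2)
  }
  per_species <- do.call(rbind, lapply(split(full, full$species), function(d) {
    v <- fit1(d$area, d$pmol)
    data.frame(species = d$species[1], slope = v[["slope"]],
               intercept = v[["intercept"]], r_squared = v[["r_squared"]])
  }))
  rownames(per_species) <- NULL
  per_species$eligible <- per_species$r_squared > r2_eligible
  memb <- if (is.null(membrane_species)) full
          else full[full$species %in% membrane_species, , drop = FALSE]
  tot <- stats::aggregate(pmol ~ area + replicate, memb, sum)
  mv <- fit1(tot$area, tot$pmol)
  counts <- do.call(rbind, lapply(split(full, full$area), function(d) {
    n_rep <- length(unique(d$replicate))
    present <- stats::aggregate(pmol ~ species, d,
                                function(v) sum(v > 0) >= n_rep / 2)
    data.frame(area = d$area[1], n_species = sum(present$pmol))
  }))
  rownames(counts) <- NULL
  structure(per_species,
            membrane_fit = as.list(mv),
            quantifiable_counts = counts[order(counts$area), ],
            class = c("linearity_report", "data.frame"))
}

#' @export
print.linearity_report <- function(x, ...) {
  mf <- attr(x, "membrane_fit")
  cat("<linearity_report> ", nrow(x), " species, ",
      sum(x$eligible), " eligible (R^2 > 0.7); membrane total R^2 = ",
      format(mf$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Group-level class composition summary
#'
#' Class-level mol% mean and SEM per sample group, plus the summed
#' lyso + PA fraction — the laser-ablation degradation signature the
#' platform monitors when comparing LMD spots with full-section controls.
#' Groups of one sample get SEM = 0 with a flag.
#'
#' @param lipidomes list of `quant_lipidome`s.
#' @param grouping character/factor of group labels, one per lipidome.
#' @param registry a `lipid_registry`.
#' @return a `group_summary` data.frame with `group`, `class_name`,
#'   `mol_percent_mean`, `mol_percent_sem`, `n`, `single_sample`; the
#'   lyso + PA sum appears as pseudo-class `"lyso+PA"`.
#' @export
group_summary <- function(lipidomes, grouping,
                          registry = default_registry()) {
  stopifnot(length(lipidomes) == length(grouping), length(lipidomes) >= 1L)
  lyso <- c(grep("^L", names(registry), value = TRUE), "PA")
  per_sample <- do.call(rbind, lapply(seq_along(lipidomes), function(i) {
    ct <- attr(lipidomes[[i]], "class_totals")
    ct <- ct[!is.na(ct$mol_percent), c("class_name", "mol_percent")]
    ct <- rbind(ct, data.frame(
      class_name = "lyso+PA",
      mol_percent = sum(ct$mol_percent[ct$class_name %in% lyso])))
    ct$group <- as.character(grouping[i])
    ct
  }))
  out <- do.call(rbind, lapply(
    split(per_sample, per_sample[c("group", "class_name")], drop = TRUE),
    function(d) data.frame(
      group = d$group[1], class_name = d$class_name[1],
      mol_percent_mean = mean(d$mol_percent),
      mol_percent_sem = if (nrow(d) > 1)
        stats::sd(d$mol_percent) / sqrt(nrow(d)) else 0,
      n = nrow(d), single_sample = nrow(d) == 1L)))
  rownames(out) <- NULL
  structure(out[order(out$group, out$class_name), ],
            class = c("group_summary", "data.frame"))
}
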