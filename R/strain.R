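#' Strain-relaxation calculus for excised fruit-skin discs
#'
#' An epidermal segment (ES) is punched from the fruit skin, the cuticular
#' membrane (CM) enzymatically isolated, and its waxes solvent-extracted to
#' give the dewaxed membrane (DCM). Each step releases in-plane elastic
#' strain, observed as area shrinkage. All apparent strains are referenced
#' to the fully relaxed (dewaxed) area A_DCM:
#' \deqn{\varepsilon'_{exc+iso} = (A - A_{CM}) / A_{DCM} \times 100}
#' \deqn{\varepsilon'_{extr} = (A_{CM} - A_{DCM}) / A_{DCM} \times 100}
#' \deqn{\varepsilon'_{tot} = \varepsilon'_{exc+iso} + \varepsilon'_{extr}}
#' The common denominator makes the components exactly additive; the
#' denominator is deliberately A_DCM in both (not A_CM) and must not be
#' "corrected". Negative strains are returned as-is, never clamped.
#'
#' @param a_initial_mm2 A: area of the excised segment before excision
#'   (the punch cross-section).
#' @param a_cm_mm2 A_CM: isolated cuticle disc area.
#' @param a_dcm_mm2 A_DCM: dewaxed disc area.
#' @return Strain in percent (all functions vectorised).
#' @name strain_calculus
NULL

check_dcm <- function(a_dcm_mm2) {
  if (any(!is.finite(a_dcm_mm2)) || any(a_dcm_mm2 <= 0))
    stop("A_DCM must be positive")
}

#' @rdname strain_calculus
#' @export
strain_exc_iso <- function(a_initial_mm2, a_cm_mm2, a_dcm_mm2) {
  check_dcm(a_dcm_mm2)
  (a_initial_mm2 - a_cm_mm2) / a_dcm_mm2 * 100
}

#' @rdname strain_calculus
#' @export
strain_extr <- function(a_cm_mm2, a_dcm_mm2) {
  check_dcm(a_dcm_mm2)
  (a_cm_mm2 - a_dcm_mm2) / a_dcm_mm2 * 100
}

#' @rdname strain_calculus
#' @param eps_exc_iso_pct,eps_extr_pct The two strain components, percent.
#' @export
strain_total <- function(eps_exc_iso_pct, eps_extr_pct) {
  eps_exc_iso_pct + eps_extr_pct
}

#' Dewaxed-membrane area reconstructed from the square-hole pattern
#'
#' After wax extraction the rim of the cuticle disc curls, so the DCM
#' outline cannot be traced directly. A square pattern of four holes
#' punched before extraction relaxes with the membrane; the DCM area is
#' the CM area scaled by the hole-pattern area ratio:
#' `A_DCM = A_CM * holes_dcm / holes_cm`.
#'
#' @param a_cm_mm2 Isolated cuticle disc area, mm^2.
#' @param holes_cm_mm2 Hole-pattern area before extraction, mm^2.
#' @param holes_dcm_mm2 Hole-pattern area after extraction, mm^2.
#' @return A_DCM, mm^2 (vectorised).
#' @export
dcm_area_from_holes <- function(a_cm_mm2, holes_cm_mm2, holes_dcm_mm2) {
  if (any(a_cm_mm2 <= 0) || any(holes_cm_mm2 <= 0) || any(holes_dcm_mm2 <= 0))
    stop("all areas must be positive")
  a_cm_mm2 * holes_dcm_mm2 / holes_cm_mm2
}

#' Strain released from an individual lenticel core
#'
#' `eps_lenticel = (A'_IL - A'_DL) / A'_DL * 100`, where A'_IL is the core
#' area per lenticel after cuticle isolation and A'_DL the core area after
#' wax extraction.
#'
#' @param a_core_isolated_mm2 Core area in the isolated cuticle disc, mm^2.
#' @param a_core_dewaxed_mm2 Core area after wax extraction, mm^2.
#' @return Strain, percent (vectorised).
#' @export
strain_lenticel <- function(a_core_isolated_mm2, a_core_dewaxed_mm2) {
  if (any(!is.finite(a_core_dewaxed_mm2)) || any(a_core_dewaxed_mm2 <= 0))
    stop("dewaxed core area must be positive")
  (a_core_isolated_mm2 - a_core_dewaxed_mm2) / a_core_dewaxed_mm2 * 100
}

#' Per-sample strains for a table of strain samples
#'
#' Computes all three apparent strains for each row. When hole-pattern
#' areas are present (`holes_cm_mm2`, `holes_dcm_mm2`), A_DCM is
#' reconstructed from them via [dcm_area_from_holes()] in preference to a
#' directly measured `a_dcm_mm2`. Negative strains are flagged, not
#' clamped.
#'
#' @param samples Data frame with `a_initial_mm2`, `a_cm_mm2` and either
#'   `a_dcm_mm2` or both hole-pattern columns; optional `sample_id`,
#'   `group`, `has_lenticels` are carried through.
#' @return The input with `a_dcm_used_mm2`, `eps_exc_iso_pct`,
#'   `eps_extr_pct`, `eps_tot_pct` and `negative_strain` columns appended.
#' @export
compute_strains <- function(samples) {
  need <- c("a_initial_mm2", "a_cm_mm2")
  if (!all(need %in% names(samples)))
    stop("`samples` needs columns ", paste(need, collapse = ", "))
  has_holes <- all(c("holes_cm_mm2", "holes_dcm_mm2") %in% names(samples)) &&
    !anyNA(samples$holes_cm_mm2) && !anyNA(samples$holes_dcm_mm2)
  a_dcm <- if (has_holes) {
    dcm_area_from_holes(samples$a_cm_mm2, samples$holes_cm_mm2,
                        samples$holes_dcm_mm2)
  } else if ("a_dcm_mm2" %in% names(samples)) {
    samples$a_dcm_mm2
  } else stop("`samples` needs `a_dcm_mm2` or hole-pattern areas")
  e1 <- strain_exc_iso(samples$a_initial_mm2, samples$a_cm_mm2, a_dcm)
  e2 <- strain_extr(samples$a_cm_mm2, a_dcm)
  out <- samples
  out$a_dcm_used_mm2 <- a_dcm
  out$eps_exc_iso_pct <- e1
  out$eps_extr_pct <- e2
  out$eps_tot_pct <- strain_total(e1, e2)
  out$negative_strain <- e1 < 0 | e2 < 0
  out
}

#' Group comparison of apparent strains (with vs. without lenticels)
#'
#' Means and standard errors of the three strain components per group,
#' plus the with/without-lenticels ratio for each component — the shape of
#' a strain-partitioning comparison table.
#'
#' @param samples Strain samples (see [compute_strains()]) with a logical
#'   `has_lenticels` column; both groups must be present with at least two
#'   samples each.
#' @return List with `by_group` (data frame: group, n, mean/SE of each
#'   strain) and `ratio_with_over_without` (named vector over the three
#'   strain components).
#' @export
compare_groups <- function(samples) {
  if (is.null(samples$has_lenticels))
    stop("`samples` needs a logical `has_lenticels` column")
  strains <- compute_strains(samples)
  for (g in c(TRUE, FALSE))
    if (sum(strains$has_lenticels == g) < 2)
      stop("need at least 2 samples ",
           if (g) "with" else "without", " lenticels")
  comp <- c("eps_exc_iso_pct", "eps_extr_pct", "eps_tot_pct")
  summ <- function(sub) {
    stats <- lapply(comp, function(v)
      c(mean(sub[[v]]), stats::sd(sub[[v]]) / sqrt(nrow(sub))))
    out <- data.frame(n = nrow(sub))
    for (i in seq_along(comp)) {
      out[[paste0("mean_", comp[i])]] <- stats[[i]][1]
      out[[paste0("se_", comp[i])]] <- stats[[i]][2]
    }
    out
  }
  with_l <- summ(strains[strains$has_lenticels, , drop = FALSE])
  without_l <- summ(strains[!strains$has_lenticels, , drop = FALSE])
  by_group <- cbind(group = c("with_lenticels", "without_lenticels"),
                    rbind(with_l, without_l))
  ratio <- vapply(comp, function(v)
    with_l[[paste0("mean_", v)]] / without_l[[paste0("mean_", v)]],
    numeric(1))
  names(ratio) <- sub("_pct$", "", sub("^eps_", "", comp))
  list(by_group = by_group, ratio_with_over_without = ratio)
}
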