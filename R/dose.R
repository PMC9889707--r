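#' Stimulation-dose conversion table
#'
#' Maps the tunable stimulation knob — mol% biotin for lipid-coated
#' scaffold (APC-ms) stimulation, or bead:cell ratio for Dynabeads — to the
#' measured anti-CD3/anti-CD28 antibody mass presented per cell (pg/cell).
#' The default table is synthetic: pg/cell proportional to mol% (100 pg per
#' mol%), with the Dynabead 3:1 entry pinned to the value of 0.1 mol%
#' (the two conditions are stimulation-dose-matched) and 1:1 / 5:1 scaled by
#' bead ratio. Supply a measured table for real data.
#'
#' @param mol_pct APC-ms mol% biotin knots (strictly increasing).
#' @param pg_per_cell pg/cell at those knots (strictly increasing).
#' @param dynabead named numeric vector: pg/cell per bead:cell ratio label
#'   (names are the ratios, e.g. `"3"` for 3:1).
#' @return Object of class `dose_conversion_table`.
#' @export
dose_conversion_table <- function(
    mol_pct = c(0.02, 0.05, 0.1, 0.15, 0.2, 0.3),
    pg_per_cell = 100 * mol_pct,
    dynabead = c("1" = 100 * 0.1 / 3, "3" = 100 * 0.1, "5" = 100 * 0.1 * 5 / 3)) {
  if (length(mol_pct) != length(pg_per_cell)) {
    stop("mol_pct and pg_per_cell must have equal length")
  }
  if (any(diff(mol_pct) <= 0) || any(diff(pg_per_cell) <= 0)) {
    stop("conversion table must be strictly increasing in both coordinates")
  }
  structure(list(mol_pct = as.numeric(mol_pct),
                 pg_per_cell = as.numeric(pg_per_cell),
                 dynabead = dynabead),
            class = "dose_conversion_table")
}

#' Convert mol% biotin to pg/cell
#'
#' Piecewise-linear interpolation between table knots; no extrapolation.
#'
#' @param mol_pct query dose(s), mol% biotin.
#' @param table a [dose_conversion_table()].
#' @return pg/cell value(s).
#' @export
mol_pct_to_pg_per_cell <- function(mol_pct, table = dose_conversion_table()) {
  rng <- range(table$mol_pct)
  if (any(mol_pct < rng[1] | mol_pct > rng[2])) {
    stop("dose outside conversion-table range [", rng[1], ", ", rng[2], "]")
  }
  stats::approx(table$mol_pct, table$pg_per_cell, xout = mol_pct,
                method = "linear", ties = "ordered")$y
}

#' Convert pg/cell back to the nearest achievable mol% biotin
#'
#' Inverse piecewise-linear lookup. Values outside the table's pg/cell range
#' are flagged rather than extrapolated.
#'
#' @param pg_per_cell query value(s).
#' @param table a [dose_conversion_table()].
#' @return data.frame with `pg_per_cell`, `mol_pct` (NA when out of range)
#'   and logical `out_of_range`.
#' @export
pg_per_cell_to_mol_pct <- function(pg_per_cell,
                                   table = dose_conversion_table()) {
  rng <- range(table$pg_per_cell)
  oob <- pg_per_cell < rng[1] | pg_per_cell > rng[2]
  mol <- rep(NA_real_, length(pg_per_cell))
  if (any(!oob)) {
    mol[!oob] <- stats::approx(table$pg_per_cell, table$mol_pct,
                               xout = pg_per_cell[!oob], method = "linear",
                               ties = "ordered")$y
  }
  data.frame(pg_per_cell = pg_per_cell, mol_pct = mol, out_of_range = oob)
}

#' Stimulation-dose descriptor
#'
#' @param stim_type `"APC-ms"` or `"Dynabead"`.
#' @param mol_pct mol% biotin (APC-ms only).
#' @param bead_ratio bead:cell ratio (Dynabead only).
#' @param table conversion table used to fill in pg/cell.
#' @return Object of class `stimulation_dose` with fields `stim_type`,
#'   `mol_pct` or `bead_ratio`, `pg_per_cell`, `label` (e.g. "A0.1", "D3")
#'   and `mol_equiv` (the mol%-scale equivalent driving dose-response laws:
#'   the dose itself for APC-ms, pg/cell mapped back through the APC-ms
#'   branch for Dynabeads).
#' @export
stimulation_dose <- function(stim_type = c("APC-ms", "Dynabead"),
                             mol_pct = NULL, bead_ratio = NULL,
                             table = dose_conversion_table()) {
  stim_type <- match.arg(stim_type)
  if (stim_type == "APC-ms") {
    if (is.null(mol_pct) || !is.null(bead_ratio)) {
      stop("APC-ms dose takes mol_pct only")
    }
    pg <- mol_pct_to_pg_per_cell(mol_pct, table)
    structure(list(stim_type = stim_type, mol_pct = mol_pct,
                   bead_ratio = NULL, pg_per_cell = pg, mol_equiv = mol_pct,
                   label = sprintf("A%g", mol_pct)),
              class = "stimulation_dose")
  } else {
    if (is.null(bead_ratio) || !is.null(mol_pct)) {
      stop("Dynabead dose takes bead_ratio only")
    }
    key <- as.character(bead_ratio)
    if (!key %in% names(table$dynabead)) {
      stop("no Dynabead entry for ratio ", bead_ratio, ":1")
    }
    pg <- unname(table$dynabead[key])
    inv <- pg_per_cell_to_mol_pct(pg, table)
    structure(list(stim_type = stim_type, mol_pct = NULL,
                   bead_ratio = bead_ratio, pg_per_cell = pg,
                   mol_equiv = inv$mol_pct,
                   label = sprintf("D%g", bead_ratio)),
              class = "stimulation_dose")
  }
}

#' @export
print.stimulation_dose <- function(x, ...) {
  cat(x$label, " (", x$stim_type, "): ", x$pg_per_cell,
      " pg/cell anti-CD3/anti-CD28\n", sep = "")
  invisible(x)
}
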