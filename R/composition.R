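.avogadro <- 6.02214076e23

## Macromolecular composition of an average exponentially growing E. coli
## cell (40-min doubling time, ~1000 fg wet mass, 0.9 um^3): per-class
## masses, aromatic-unit mole percentages (protein/RNA/DNA), metabolite
## concentrations (mM), and the transcribed per-unit aromatic counts
## (x1e6 per cell).
.ecoli_units <- data.frame(
  class = c(rep("protein", 3), rep("RNA", 4), rep("DNA", 4),
            rep("metabolites", 8)),
  unit = c("Phe", "Trp", "Tyr",
           "A", "C", "G", "U",
           "A", "C", "G", "T",
           "A", "C", "G", "T", "U", "Phe", "Trp", "Tyr"),
  mol_pct = c(3.46, 1.06, 2.58,
              24.8, 21.8, 32.4, 21.0,
              24.5, 24.6, 26.2, 24.7,
              rep(NA_real_, 8)),
  conc_mM = c(rep(NA_real_, 11),
              16.0, 2.75, 5.85, 4.98, 22.7, 2.00, 1.33, 3.22),
  units_1e6 = c(31.8, 9.74, 23.6,
                26.2, 23.0, 34.2, 22.2,
                4.07, 4.08, 4.35, 4.10,
                10.7, 1.84, 3.91, 3.33, 15.2, 0.012, 0.0008, 0.019),
  stringsAsFactors = FALSE
)

.ecoli_classes <- data.frame(
  class = c("protein", "RNA", "DNA", "metabolites", "other", "water"),
  pct_mass = c(16.5, 6, 0.9, 7, 5.7, 63.9),
  mass_fg = c(165, 60, 9, 70, 57, 639),
  units_1e6 = c(65.2, 106, 16.6, 36.4, NA, NA),
  stringsAsFactors = FALSE
)

#' Aromatic unit count from macromolecule mass
#'
#' `count = mass_fg * 1e-15 / mean_residue_mass_Da * N_A * fraction`:
#' the number of aromatic (DUV-resonant) residues contributed per cell by
#' a macromolecule class of given mass and aromatic mole fraction.
#'
#' @param mass_fg class mass per cell, femtograms.
#' @param mean_residue_mass_Da mean residue mass, Da.
#' @param aromatic_mole_fraction fraction of residues that are aromatic
#'   (0-1].
#' @return Residue count per cell.
#' @examples
#' units_from_mass(165, 108.2, 0.071) / 1e6  # ~65 million protein AAAs
#' @export
units_from_mass <- function(mass_fg, mean_residue_mass_Da,
                            aromatic_mole_fraction) {
  if (any(c(mass_fg, mean_residue_mass_Da, aromatic_mole_fraction) <= 0) &&
      aromatic_mole_fraction != 0)
    stop("all inputs must be > 0", call. = FALSE)
  if (aromatic_mole_fraction > 1)
    stop("aromatic_mole_fraction must be <= 1", call. = FALSE)
  mass_fg * 1e-15 / mean_residue_mass_Da * .avogadro * aromatic_mole_fraction
}

#' Molecule count from a cellular concentration
#'
#' `count = conc_mM * 1e-3 * volume_fL * 1e-15 * N_A`: molecules per cell
#' for a metabolite at a given intracellular concentration.
#'
#' @param conc_mM concentration, mM.
#' @param volume_fL conversion volume, fL. The per-unit counts of the
#'   reference budget imply ~1.113 fL rather than the nominal 0.9 um^3
#'   cell volume; see [cell_budget()].
#' @return Molecule count per cell.
#' @examples
#' units_from_concentration(16.0, 1.113) / 1e6  # ~10.7 million
#' @export
units_from_concentration <- function(conc_mM, volume_fL) {
  if (any(c(conc_mM, volume_fL) < 0))
    stop("inputs must be >= 0", call. = FALSE)
  conc_mM * 1e-3 * volume_fL * 1e-15 * .avogadro
}

#' E. coli aromatic-residue budget
#'
#' Builds the per-class, per-unit budget of DUV-resonant aromatic residues
#' in an average exponentially growing *E. coli* cell. In `"transcribed"`
#' mode the tabulated per-unit counts are taken as given; in `"derived"`
#' mode they are recomputed from class masses, mole percentages and
#' metabolite concentrations via [units_from_mass()] and
#' [units_from_concentration()], using mean residue masses calibrated so
#' class totals match the tabulated ones (protein 108.2, RNA 340, DNA
#' 327 Da).
#'
#' @param mode `"transcribed"` (default) or `"derived"`.
#' @param cell_volume_fL nominal cell volume, fL (0.9).
#' @param metabolite_volume_fL volume used for concentration-to-count
#'   conversion (default 1.113 fL, the value implied by the tabulated
#'   metabolite counts).
#' @param residue_mass_Da named vector of mean residue masses for protein,
#'   RNA and DNA (derived mode).
#' @return Object of class `cell_budget`: list with `units` (per-unit data
#'   frame incl. `units_per_cell`), `classes` (per-class masses, %mass and
#'   subtotal counts), `mode`, volumes.
#' @export
cell_budget <- function(mode = c("transcribed", "derived"),
                        cell_volume_fL = 0.9, metabolite_volume_fL = 1.113,
                        residue_mass_Da = c(protein = 108.2, RNA = 340,
                                            DNA = 327)) {
  mode <- match.arg(mode)
  units <- .ecoli_units
  classes <- .ecoli_classes
  if (mode == "transcribed") {
    units$units_per_cell <- units$units_1e6 * 1e6
  } else {
    upc <- numeric(nrow(units))
    for (k in seq_len(nrow(units))) {
      cl <- units$class[k]
      if (cl == "metabolites") {
        ## the tabulated AAA metabolite concentrations are inconsistent
        ## with their own tabulated counts by ~2 orders of magnitude
        ## (the AAA pool is tens of thousands of molecules per cell, not
        ## millions); keep the transcribed counts for those rows
        upc[k] <- if (units$unit[k] %in% c("Phe", "Trp", "Tyr"))
          units$units_1e6[k] * 1e6
        else
          units_from_concentration(units$conc_mM[k], metabolite_volume_fL)
      } else {
        mass <- classes$mass_fg[classes$class == cl]
        upc[k] <- units_from_mass(mass, residue_mass_Da[[cl]],
                                  units$mol_pct[k] / 100)
      }
    }
    units$units_per_cell <- upc
    for (cl in c("protein", "RNA", "DNA", "metabolites"))
      classes$units_1e6[classes$class == cl] <-
        sum(upc[units$class == cl]) / 1e6
  }
  if (abs(sum(classes$pct_mass) - 100) > 0.2)
    stop("class mass percentages must sum to 100 +/- 0.2", call. = FALSE)
  structure(list(units = units, classes = classes, mode = mode,
                 cell_volume_fL = cell_volume_fL,
                 metabolite_volume_fL = metabolite_volume_fL),
            class = "cell_budget")
}

#' @export
print.cell_budget <- function(x, ...) {
  cat(sprintf("E. coli aromatic-residue budget (%s mode)\n", x$mode))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

## round half away from zero, for comparison against printed figures
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Summary fractions of the aromatic-residue budget
#'
#' Totals and headline fractions: total DUV-resonant aromatic units per
#' cell; the nucleotide vs amino-acid split; the percentage of nucleobases
#' sequestered in nucleic acids (RNA + DNA units over all nucleobase
#' units); and the percentage of aromatic amino acids residing in protein.
#' Class subtotals are used as tabulated; the per-unit metabolite rows sum
#' to ~35.0e6 rather than the tabulated subtotal 36.4e6 — both numbers are
#' reported and the discrepancy flagged.
#'
#' @param budget a [cell_budget].
#' @return List with `total_units`, `pct_nucleotide`, `pct_amino_acid`,
#'   `pct_nucleobases_in_nucleic_acids`, `pct_aaa_in_protein`,
#'   `metabolite_subtotal_units`, `metabolite_units_row_sum`,
#'   `metabolite_subtotal_consistent`.
#' @examples
#' budget_summary(cell_budget())
#' @export
budget_summary <- function(budget) {
  stopifnot(inherits(budget, "cell_budget"))
  cls <- budget$classes
  un <- budget$units
  sub <- function(cl) cls$units_1e6[cls$class == cl] * 1e6
  aaa_metab <- sum(un$units_per_cell[un$class == "metabolites" &
                                       un$unit %in% c("Phe", "Trp", "Tyr")])
  metab_total <- sub("metabolites")
  metab_rows <- sum(un$units_per_cell[un$class == "metabolites"])
  nb_metab <- metab_total - aaa_metab
  nucleic <- sub("RNA") + sub("DNA")
  protein <- sub("protein")
  total <- protein + nucleic + metab_total
  if (total <= 0) stop("zero totals in budget", call. = FALSE)
  list(total_units = total,
       pct_nucleotide = 100 * (nucleic + nb_metab) / total,
       pct_amino_acid = 100 * (protein + aaa_metab) / total,
       pct_nucleobases_in_nucleic_acids = 100 * nucleic / (nucleic + nb_metab),
       pct_aaa_in_protein = 100 * protein / (protein + aaa_metab),
       metabolite_subtotal_units = metab_total,
       metabolite_units_row_sum = metab_rows,
       metabolite_subtotal_consistent =
         abs(metab_total - metab_rows) / metab_total < 0.01)
}

## approximate molar masses (g/mol) of mixture components
.component_mw <- c(oligomer = 330,                     # per nucleotide residue
                   dATP = 491.2, dCTP = 467.2, dGTP = 507.2, dTTP = 482.2,
                   UTP = 484.2,
                   Phe = 165.2, Trp = 204.2, Tyr = 181.2)

#' Artificial cell-mimic mixture recipe
#'
#' Allocates a total concentration across 13 molecular standards in
#' proportion to the budget's residue counts: DNA/RNA oligomer standards
#' carry the A, C, G, T, U residues of macromolecular nucleic acid,
#' dATP/dCTP/dGTP/dTTP/UTP carry the free-nucleotide pool, and free Phe,
#' Trp, Tyr carry the aromatic amino acids of protein plus metabolome.
#'
#' @param budget a [cell_budget].
#' @param total_mM total mixture concentration (default 1.00 mM).
#' @return Object of class `mixture_recipe`: data frame with `component`,
#'   `class`, `residue`, `conc_mM`; attributes `total_mM` and
#'   `implied_mass_fg` (mass in the nominal 0.9 um^3 cell volume given
#'   approximate component molar masses).
#' @export
mixture_recipe <- function(budget, total_mM = 1.00) {
  stopifnot(inherits(budget, "cell_budget"))
  un <- budget$units
  count <- function(cl, u) sum(un$units_per_cell[un$class %in% cl &
                                                   un$unit == u])
  bases <- c("A", "C", "G", "T", "U")
  rows <- list()
  for (b in bases)
    rows[[length(rows) + 1L]] <-
      data.frame(component = paste0("oligo-", b), class = "oligomer",
                 residue = b, count = count(c("RNA", "DNA"), b))
  free_names <- c(A = "dATP", C = "dCTP", G = "dGTP", T = "dTTP", U = "UTP")
  for (b in bases)
    rows[[length(rows) + 1L]] <-
      data.frame(component = free_names[[b]], class = "free_nucleotide",
                 residue = b, count = count("metabolites", b))
  for (a in c("Phe", "Trp", "Tyr"))
    rows[[length(rows) + 1L]] <-
      data.frame(component = a, class = "amino_acid", residue = a,
                 count = count(c("protein", "metabolites"), a))
  tab <- do.call(rbind, rows)
  if (sum(tab$count) <= 0) stop("budget totals must be > 0", call. = FALSE)
  tab$conc_mM <- total_mM * tab$count / sum(tab$count)
  tab$count <- NULL
  mw <- ifelse(tab$class == "oligomer", .component_mw[["oligomer"]],
               .component_mw[tab$component])
  # c [mM] * V [0.9 fL] * MW -> fg:  c*1e-3 mol/L * 0.9e-15 L * MW g/mol * 1e15 fg/g
  implied_mass <- sum(tab$conc_mM * 1e-3 * budget$cell_volume_fL * mw)
  structure(tab, class = c("mixture_recipe", "data.frame"),
            total_mM = total_mM, implied_mass_fg = implied_mass)
}

#' @export
print.mixture_recipe <- function(x, ...) {
  cat(sprintf("Artificial mixture, total %.2f mM (~%.2f fg per %s):\n",
              attr(x, "total_mM"), attr(x, "implied_mass_fg"),
              "0.9 um^3"))
  print.data.frame(cbind(x[c("component", "class", "residue")],
                         conc_mM = signif(x$conc_mM, 4)), row.names = FALSE)
  invisible(x)
}

#' Cells interrogated per laser spot
#'
#' For a dried droplet of cell suspension probed by a laser spot:
#' `count = deposited_cells * (laser_diameter / dry_spot_diameter)^2`,
#' assuming a roughly uniform distribution of cells over the dry spot.
#'
#' @param volume_uL deposited volume, uL.
#' @param density_per_mL cell density of the suspension, cells/mL.
#' @param dry_spot_diameter_mm dry spot diameter, mm.
#' @param laser_diameter_um laser spot diameter, um.
#' @return Expected number of cells in the laser spot.
#' @examples
#' cells_per_spot(2, 1.6e8, 2, 68)  # ~370
#' @export
cells_per_spot <- function(volume_uL, density_per_mL, dry_spot_diameter_mm,
                           laser_diameter_um) {
  vals <- c(volume_uL, density_per_mL, dry_spot_diameter_mm,
            laser_diameter_um)
  if (any(vals < 0)) stop("all geometry fields must be >= 0", call. = FALSE)
  if (any(vals[-2] <= 0)) stop("geometry must be > 0", call. = FALSE)
  if (laser_diameter_um / 1000 > dry_spot_diameter_mm)
    stop("laser spot cannot exceed the dry spot", call. = FALSE)
  deposited <- volume_uL * 1e-3 * density_per_mL
  deposited * (laser_diameter_um / 1000 / dry_spot_diameter_mm)^2
}

#' Base composition of a DNA/RNA sequence
#'
#' Exact per-base counts and molar percentages of a nucleotide sequence
#' string (alphabet A, C, G, T, U).
#'
#' @param sequence nonempty character string.
#' @return List with `counts` (named integer), `percent` (unrounded) and
#'   `percent_rounded` (integer percent, half away from zero).
#' @examples
#' base_composition("CAATTGTACTAGCCGGATC")$counts  # A5 C5 G4 T5
#' @export
base_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("nonempty sequence string required", call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U"))
  if (length(bad) > 0L)
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1L]],
                 bad[1L]), call. = FALSE)
  counts <- table(factor(chars, levels = c("A", "C", "G", "T", "U")))
  counts <- counts[counts > 0]
  pct <- 100 * as.numeric(counts) / length(chars)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       percent = stats::setNames(pct, names(counts)),
       percent_rounded = stats::setNames(as.integer(round_half_away(pct)),
                                         names(counts)))
}
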