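#' Default extracellular-loop region definitions
#'
#' Bundled spans for the extracellular loops and adjacent transmembrane
#' boundary residues of the GLP-1 receptor, in protein-sequence numbering:
#' ECL1 201-223 (23 residues, L201-S223), ECL2 285-307 (23 residues,
#' G285-L307), ECL3 372-387 (16 residues, D372-E387).
#'
#' @return A `RegionDefinition` tibble with columns `region`, `start`,
#'   `end` (inclusive).
#' @export
default_regions <- function() {
  tibble::tibble(
    region = c("ECL1", "ECL2", "ECL3"),
    start = c(201L, 285L, 372L),
    end = c(223L, 307L, 387L))
}

#' Assign residue positions to receptor regions
#'
#' Maps each residue position to exactly one named region, or `"other"`
#' when it falls outside all spans. Regions must not overlap.
#'
#' @param positions Integer residue positions (1-based protein numbering).
#' @param regions Region table with `region`, `start`, `end`; defaults to
#'   [default_regions()].
#' @return Tibble `position`, `region`, with per-region residue counts (for
#'   the full spans) in `attr(, "region_counts")`.
#' @export
assign_regions <- function(positions, regions = default_regions()) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)),
            all(regions$end >= regions$start), all(positions >= 1))
  o <- regions[order(regions$start), ]
  if (nrow(o) > 1 && any(o$start[-1] <= o$end[-nrow(o)])) {
    stop("region definitions overlap")
  }
  reg <- rep("other", length(positions))
  for (i in seq_len(nrow(regions))) {
    hit <- positions >= regions$start[i] & positions <= regions$end[i]
    reg[hit] <- regions$region[i]
  }
  out <- tibble::tibble(position = as.integer(positions), region = reg)
  attr(out, "region_counts") <- stats::setNames(
    regions$end - regions$start + 1L, regions$region)
  out
}

#' Summarise per-ligand heat categories into a per-residue class
#'
#' Collapses the per-ligand heat categories of one residue (for one
#' measure) into the summary classes used for the combined structure maps:
#' `global_all_ligands` when every assayed ligand is reduced,
#' `selective_single_ligand` when exactly one is, `shared_two_ligands` when
#' exactly two (of more) are, `enhanced` when at least one ligand is
#' enhanced and none reduced, `mixed` when reduced and enhanced coexist
#' (e.g. a mutation that boosts one peptide's signaling while crippling
#' another's), and `none` otherwise. Ligands with `not_determined`
#' categories do not count as assayed. The result is invariant to ligand
#' order.
#'
#' @param categories Tibble with columns `position`, `ligand_id`,
#'   `category` (values from [heat_levels()]).
#' @return Tibble `position`, `n_assayed`, `n_reduced`, `n_enhanced`,
#'   `summary_class`.
#' @export
summarize_across_ligands <- function(categories) {
  stopifnot(all(c("position", "ligand_id", "category") %in%
                  names(categories)))
  reduced_set <- c("fold_3_5", "fold_5_10", "fold_10_30", "fold_gt_30")
  per <- split(categories, categories$position)
  rows <- purrr::map(per, function(d) {
    cat <- as.character(d$category)
    assayed <- cat != "not_determined"
    n_red <- sum(cat %in% reduced_set)
    n_enh <- sum(cat == "enhanced")
    cls <- if (n_red > 0 && n_enh > 0) "mixed"
      else if (n_enh > 0) "enhanced"
      else if (n_red == 0) "none"
      else if (n_red == sum(assayed)) "global_all_ligands"
      else if (n_red == 1) "selective_single_ligand"
      else if (n_red == 2) "shared_two_ligands"
      else "shared_two_ligands"  # 3+ reduced of a larger assayed panel
    tibble::tibble(position = d$position[1],
                   n_assayed = sum(assayed), n_reduced = n_red,
                   n_enhanced = n_enh, summary_class = cls)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$position)
}

# sentinel B-factor for residues not covered by the annotation set
B_SENTINEL <- -9

#' Write a structure heatmap as PDB B-factor codes
#'
#' Projects per-residue heat categories onto a 3D structure by writing each
#' annotated residue's integer category code ([heat_levels()]: 0 no_effect
#' ... 4 fold_gt_30, 5 enhanced, -1 not_determined) into the B-factor
#' column of all its atoms, so any molecular viewer can color the surface
#' by mutational effect. Unannotated residues receive the sentinel value
#' -9. A companion TSV lists position, region, category and code, and the
#' category -> color legend ships as
#' `system.file("extdata/heat_legend.json", package = "alascan")`.
#'
#' @param annotations Tibble with `position`, `category` (and optionally
#'   `region`).
#' @param pdb_file Input PDB path.
#' @param out_pdb,out_tsv Output paths (PDB with recoded B-factors;
#'   tab-separated attribute table).
#' @param offset Structure residue number = annotation position + offset.
#' @return Invisibly, a tibble of the written annotations. Warns listing
#'   annotation positions absent from the structure; errors if more than
#'   20% are absent (suggesting a numbering offset).
#' @export
write_structure_annotation <- function(annotations, pdb_file, out_pdb,
                                       out_tsv = NULL, offset = 0) {
  stopifnot(all(c("position", "category") %in% names(annotations)))
  pdb <- bio3d::read.pdb(pdb_file)
  resno <- pdb$atom$resno
  target <- annotations$position + offset
  missing <- setdiff(target, unique(resno))
  if (length(target) > 0 && length(missing) / length(target) > 0.2) {
    stop("more than 20% of annotated positions (",
         paste(missing - offset, collapse = ", "),
         ") are absent from the structure; check the numbering offset")
  }
  if (length(missing) > 0) {
    warning("positions absent from structure: ",
            paste(missing - offset, collapse = ", "))
  }
  code <- heat_levels()[as.character(annotations$category)]
  b <- rep(B_SENTINEL, length(resno))
  i <- match(resno, target)
  hit <- !is.na(i)
  b[hit] <- code[i[hit]]
  pdb$atom$b <- b
  bio3d::write.pdb(pdb, file = out_pdb)

  written <- tibble::tibble(
    position = annotations$position,
    region = if ("region" %in% names(annotations)) annotations$region
             else NA_character_,
    category = as.character(annotations$category),
    code = as.integer(code))
  written <- written[!written$position %in% (missing - offset), ]
  if (!is.null(out_tsv)) readr::write_tsv(written, out_tsv)
  invisible(written)
}

#' Read heat categories back from an annotated PDB
#'
#' Inverse of [write_structure_annotation()]: recovers the per-residue
#' category from the B-factor column, ignoring sentinel residues.
#'
#' @param pdb_file Annotated PDB path.
#' @param offset Structure residue number = annotation position + offset.
#' @return Tibble `position`, `code`, `category`.
#' @export
read_structure_annotation <- function(pdb_file, offset = 0) {
  pdb <- bio3d::read.pdb(pdb_file)
  a <- pdb$atom
  per <- dplyr::summarise(dplyr::group_by(a, .data$resno),
                          code = round(.data$b[1]), .groups = "drop")
  per <- per[per$code != B_SENTINEL, ]
  lv <- heat_levels()
  tibble::tibble(
    position = as.integer(per$resno - offset),
    code = as.integer(per$code),
    category = names(lv)[match(per$code, lv)])
}

#' Generate a synthetic C-alpha trace structure
#'
#' Builds an idealised alpha-helical C-alpha trace (one ALA residue per
#' requested position) and writes it as a standard PDB file. This is a
#' synthetic stand-in structure for exercising the annotation writer; it
#' carries no biological geometry beyond helical spacing.
#'
#' @param positions Residue numbers to include.
#' @param path Output PDB path.
#' @param chain Chain identifier (default `"A"`).
#' @return The path, invisibly.
#' @export
make_synthetic_structure <- function(positions, path, chain = "A") {
  n <- length(positions)
  t <- seq_len(n)
  xyz <- as.numeric(rbind(2.3 * cos(t * 100 * pi / 180),
                          2.3 * sin(t * 100 * pi / 180),
                          1.5 * t))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = as.integer(positions), resid = rep("ALA", n),
    eleno = seq_len(n), elety = rep("CA", n),
    chain = rep(chain, n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}
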