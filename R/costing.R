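# Tiered synthesis/sequencing cost model.
#
# Oligonucleotide synthesis is priced per nucleotide in two tiers (short
# oligos are cheaper per base), and each recombinant clone incurs one
# insert-sequencing charge. The per-residue cost of a biosynthetic peptide
# of n residues is then
#
#   ((3n + 9) x 2 x price + sequencing) / n
#
# since both strands of the 3n + 9 nt duplex are synthesised. With the
# default prices this gives 9.80 CNY/aa for a 16-mer (57 nt strands) and
# 12.40 CNY/aa for an 8-mer (33 nt strands).

#' Cost model parameters
#'
#' @param price_short CNY per nt for oligos shorter than `tier_threshold`.
#' @param price_long CNY per nt for longer oligos.
#' @param tier_threshold Tier boundary in nt; an oligo of exactly this
#'   length is priced at the short tier.
#' @param sequencing_per_clone CNY per clone for insert sequencing.
#' @param fx_cny_per_usd CNY per USD used for reporting (7.0 reproduces the
#'   quoted USD figures; a config value, not an exchange-rate claim).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(price_short = 1.20, price_long = 2.00,
                       tier_threshold = 60L, sequencing_per_clone = 20,
                       fx_cny_per_usd = 7.0) {
  stopifnot(price_short > 0, price_long > 0, tier_threshold > 0,
            sequencing_per_clone >= 0, fx_cny_per_usd > 0)
  structure(
    list(price_short = price_short, price_long = price_long,
         tier_threshold = as.integer(tier_threshold),
         sequencing_per_clone = sequencing_per_clone,
         fx_cny_per_usd = fx_cny_per_usd),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf(
    "<cost_model> %.2f CNY/nt (<= %d nt), %.2f CNY/nt above; sequencing %.2f CNY/clone\n",
    x$price_short, x$tier_threshold, x$price_long, x$sequencing_per_clone
  ))
  invisible(x)
}

#' Synthesis price of one oligo
#'
#' @param length_nt Oligo length in nt (>= 0).
#' @param model A [cost_model()].
#' @return Price in CNY.
#' @examples
#' oligo_price(57)  # 68.40
#' oligo_price(63)  # 126.00
#' @export
oligo_price <- function(length_nt, model = cost_model()) {
  stopifnot(inherits(model, "cost_model"))
  if (any(length_nt < 0)) stop("oligo length must be >= 0", call. = FALSE)
  rate <- ifelse(length_nt <= model$tier_threshold,
                 model$price_short, model$price_long)
  length_nt * rate
}

#' Per-residue cost of one biosynthetic peptide
#'
#' Two strands of `3n + 9` nt plus one sequencing charge, divided by the
#' peptide length.
#'
#' @param peptide_len Peptide length in residues (>= 1).
#' @param model A [cost_model()].
#' @return A list with `cny_per_aa`, `usd_per_aa` and `strand_nt`.
#' @examples
#' per_aa_cost(16)$cny_per_aa  # 9.80
#' per_aa_cost(8)$cny_per_aa   # 12.40
#' @export
per_aa_cost <- function(peptide_len, model = cost_model()) {
  stopifnot(peptide_len >= 1)
  strand_nt <- 3 * peptide_len + 9
  cny <- (2 * oligo_price(strand_nt, model) + model$sequencing_per_clone) /
    peptide_len
  list(cny_per_aa = cny, usd_per_aa = cny / model$fx_cny_per_usd,
       strand_nt = strand_nt)
}

#' Cost report for a design sheet
#'
#' @param design A design-sheet `data.frame` (columns `tile_id`,
#'   `peptide`).
#' @param model A [cost_model()].
#' @return A list with `per_tile` (data.frame: tile_id, peptide_len,
#'   strand_nt, oligos_cny, sequencing_cny, total_cny, total_usd) and
#'   `totals` (named list of CNY/USD sums).
#' @export
design_cost_report <- function(design, model = cost_model()) {
  if (is.null(design) || nrow(design) == 0L) {
    per_tile <- data.frame(
      tile_id = character(0), peptide_len = integer(0), strand_nt = integer(0),
      oligos_cny = numeric(0), sequencing_cny = numeric(0),
      total_cny = numeric(0), total_usd = numeric(0), stringsAsFactors = FALSE
    )
    return(list(per_tile = per_tile,
                totals = list(cny = 0, usd = 0, n_tiles = 0L)))
  }
  plen <- nchar(design$peptide)
  strand_nt <- 3L * plen + 9L
  oligos <- 2 * oligo_price(strand_nt, model)
  total <- oligos + model$sequencing_per_clone
  per_tile <- data.frame(
    tile_id = design$tile_id, peptide_len = plen, strand_nt = strand_nt,
    oligos_cny = oligos, sequencing_cny = model$sequencing_per_clone,
    total_cny = total, total_usd = total / model$fx_cny_per_usd,
    stringsAsFactors = FALSE
  )
  list(per_tile = per_tile,
       totals = list(cny = sum(total), usd = sum(total) / model$fx_cny_per_usd,
                     n_tiles = nrow(design)))
}
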