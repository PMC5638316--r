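# Plasmid/digest/fusion arithmetic used to screen recombinant clones.
#
# Only cut-to-cut distances are modelled (no base-resolution vector map):
# the BamHI/SalI double digest of the expression vector releases a stuffer
# and a backbone whose lengths sum to the circular length. pXXGST-1 carries
# a 6 bp stuffer (4190 + 6 = 4196 bp), so its double-cut backbone is nearly
# impossible to purify away from single-cut plasmid; pXXGST-3 carries the
# 315 bp HPV18-E7 ORF plus flanking bases (stuffer 321 bp, 4190 + 321 =
# 4511 bp), making the two products easy to separate on a gel.

#' Plasmid model
#'
#' @param name Plasmid label.
#' @param backbone_len Cut-to-cut length (bp) of the long arc between the
#'   BamHI and SalI cut positions.
#' @param stuffer_len Cut-to-cut length (bp) across the cloning region.
#' @return An object of class `plasmid_model` with `circular_len ==
#'   backbone_len + stuffer_len`.
#' @examples
#' plasmid_model("pXXGST-1", 4190, 6)
#' @seealso [pxxgst_plasmids()] for the built-in vectors.
#' @export
plasmid_model <- function(name, backbone_len, stuffer_len) {
  backbone_len <- as.integer(backbone_len)
  stuffer_len <- as.integer(stuffer_len)
  stopifnot(backbone_len > 0L, stuffer_len > 0L)
  structure(
    list(name = name, backbone_len = backbone_len, stuffer_len = stuffer_len,
         circular_len = backbone_len + stuffer_len),
    class = "plasmid_model"
  )
}

#' @export
print.plasmid_model <- function(x, ...) {
  cat(sprintf("<plasmid_model> %s: %d bp circular (backbone %d + stuffer %d)\n",
              x$name, x$circular_len, x$backbone_len, x$stuffer_len))
  invisible(x)
}

#' Built-in pXXGST expression vectors
#'
#' @return Named list of [plasmid_model()]s: `pXXGST-1` (6 bp stuffer,
#'   4196 bp total) and `pXXGST-3` (321 bp E7 stuffer, 4511 bp total).
#' @export
pxxgst_plasmids <- function() {
  list(
    "pXXGST-1" = plasmid_model("pXXGST-1", backbone_len = 4190L, stuffer_len = 6L),
    "pXXGST-3" = plasmid_model("pXXGST-3", backbone_len = 4190L, stuffer_len = 321L)
  )
}

#' Predict restriction-digest fragments
#'
#' @param plasmid A [plasmid_model()].
#' @param completeness `"double_cut"`, `"single_cut"` or `"uncut"`.
#' @return A list of class `digest_result` with `completeness`, `fragments`
#'   (bp lengths summing to the circular length) and `circular` (TRUE only
#'   for uncut plasmid).
#' @examples
#' predict_digest(pxxgst_plasmids()[["pXXGST-1"]], "double_cut")  # 4190 + 6
#' @export
predict_digest <- function(plasmid,
                           completeness = c("double_cut", "single_cut", "uncut")) {
  stopifnot(inherits(plasmid, "plasmid_model"))
  completeness <- match.arg(completeness)
  fragments <- switch(completeness,
    double_cut = c(plasmid$backbone_len, plasmid$stuffer_len),
    single_cut = plasmid$circular_len,
    uncut = plasmid$circular_len
  )
  structure(
    list(completeness = completeness, fragments = fragments,
         circular = completeness == "uncut"),
    class = "digest_result"
  )
}

#' Ligate an insert into a digested backbone
#'
#' The insert's cut-to-cut contribution is the plus-strand length of a
#' designed duplex (top strand, cohesive ends included), or a given bp
#' count for a named stuffer. This convention reproduces 4196 = 4190 + 6
#' and 4511 = 4190 + 321 without a base-level vector map.
#'
#' @param backbone_len Backbone cut-to-cut length (bp).
#' @param insert An `oligo_pair` or a positive bp count.
#' @param name Name for the resulting construct.
#' @return A [plasmid_model()] for the circular ligation product.
#' @examples
#' ligate(4190, build_oligo_pair("P1", "YYGVGDYP"))$circular_len  # 4223
#' @export
ligate <- function(backbone_len, insert, name = "r-plasmid") {
  ins_len <- if (inherits(insert, "oligo_pair")) {
    nchar(insert$plus_strand)
  } else {
    as.integer(insert)
  }
  if (is.na(ins_len) || ins_len <= 0L) {
    stop("insert length must be positive", call. = FALSE)
  }
  plasmid_model(name, backbone_len = backbone_len, stuffer_len = ins_len)
}

#' Fusion protein expressed by a construct
#'
#' The carrier is the truncated 188-residue GST (GST188). A recombinant
#' clone appends its peptide (GST196 for an 8-mer); a self-ligated
#' pXXGST-1 clone reads through the cloning site into the GSVD tetrapeptide
#' (GST192); pXXGST-2 expresses the bare carrier; the GST188-E7 fusion
#' (105 extra residues, theoretical) does not express.
#'
#' @param construct_kind One of `"r_clone"`, `"self_ligation_gsvd"`,
#'   `"carrier_only"`, `"carrier_e7"`.
#' @param peptide_len Appended peptide length in residues; used only for
#'   `r_clone`.
#' @return A list of class `fusion_product` with `carrier_res`,
#'   `appended_res`, `total_res`, `est_mass` (kDa, count method),
#'   `in_weak_window` and `expressed`.
#' @examples
#' fusion_product("r_clone", 8)$total_res          # 196
#' fusion_product("self_ligation_gsvd")$total_res  # 192
#' @export
fusion_product <- function(construct_kind = c("r_clone", "self_ligation_gsvd",
                                              "carrier_only", "carrier_e7"),
                           peptide_len = 0L) {
  construct_kind <- match.arg(construct_kind)
  peptide_len <- as.integer(peptide_len)
  if (is.na(peptide_len) || peptide_len < 0L) {
    stop("peptide_len must be a non-negative residue count", call. = FALSE)
  }
  carrier <- 188L
  appended <- switch(construct_kind,
    r_clone = peptide_len,
    self_ligation_gsvd = 4L,   # GSVD read-through
    carrier_only = 0L,
    carrier_e7 = 105L          # theoretical; the fusion fails to express
  )
  total <- carrier + appended
  mass <- estimate_mass(total)
  structure(
    list(
      construct_kind = construct_kind,
      carrier_res = carrier,
      appended_res = appended,
      total_res = total,
      est_mass = mass,
      in_weak_window = in_weak_window(mass),
      expressed = construct_kind != "carrier_e7"
    ),
    class = "fusion_product"
  )
}

#' @export
print.fusion_product <- function(x, ...) {
  cat(sprintf(
    "<fusion_product> %s: GST188 + %d aa = %d aa, ~%.2f kDa%s%s\n",
    x$construct_kind, x$appended_res, x$total_res, x$est_mass,
    if (x$in_weak_window) " (weak antigenic window)" else "",
    if (!x$expressed) " [not expressed]" else ""
  ))
  invisible(x)
}

#' Approximate protein mass in kDa
#'
#' With only a residue count, uses the average-residue approximation
#' `count x 0.110 kDa + 0.018` (one water). With a sequence, sums standard
#' average residue masses plus water. Both are returned in kDa (print
#' methods round to two decimals), the method recorded in the `"method"`
#' attribute.
#'
#' @param x Residue count (single number) or a residue string.
#' @return Mass in kDa.
#' @examples
#' estimate_mass(105)  # ~11.57, the E7-scale anchor
#' estimate_mass("G")  # 0.075
#' @export
estimate_mass <- function(x) {
  if (is.character(x)) {
    x <- toupper(x)
    validate_residues(x, what = "sequence")
    chars <- strsplit(x, "")[[1]]
    kda <- (sum(RESIDUE_MASS_DA[chars]) + WATER_MASS_DA) / 1000
    method <- "sequence"
  } else {
    n <- as.integer(x)
    if (is.na(n) || n < 1L) stop("residue count must be >= 1", call. = FALSE)
    kda <- n * 0.110 + 0.018
    method <- "count"
  }
  structure(kda, method = method)
}

#' @noRd
in_weak_window <- function(mass_kda, bounds = c(21, 30)) {
  mass_kda >= bounds[1] & mass_kda <= bounds[2]
}

#' Gel-screening decision for a candidate clone
#'
#' A candidate fusion is called `distinct` from the reference when the
#' estimated mass difference is at least `threshold_kda`. The default
#' 0.8 kDa reflects what SDS-15% PAGE resolves in practice: an 8-residue
#' increment (~0.9 kDa over GST188) is visible, the 4-residue GSVD
#' read-through (~0.4 kDa) is not. Both products' positions relative to
#' the 21-30 kDa weak-antigenic window are reported.
#'
#' @param candidate,reference [fusion_product()]s (same estimation method).
#' @param threshold_kda Minimum resolvable mass difference (kDa).
#' @return A list of class `screen_decision` with `call`
#'   (`"distinct"`/`"indistinct"`), `delta_kda`, and the weak-window flags.
#' @examples
#' screen_decision(fusion_product("r_clone", 8), fusion_product("carrier_only"))
#' @export
screen_decision <- function(candidate, reference, threshold_kda = 0.8) {
  stopifnot(inherits(candidate, "fusion_product"),
            inherits(reference, "fusion_product"))
  if (attr(candidate$est_mass, "method") != attr(reference$est_mass, "method")) {
    stop("candidate and reference masses must use the same estimation method",
         call. = FALSE)
  }
  delta <- abs(as.numeric(candidate$est_mass) - as.numeric(reference$est_mass))
  structure(
    list(
      call = if (delta >= threshold_kda) "distinct" else "indistinct",
      delta_kda = round(delta, 2),
      threshold_kda = threshold_kda,
      candidate_in_weak_window = candidate$in_weak_window,
      reference_in_weak_window = reference$in_weak_window
    ),
    class = "screen_decision"
  )
}

#' @export
print.screen_decision <- function(x, ...) {
  cat(sprintf("<screen_decision> %s (|delta| = %.2f kDa, threshold %.2f)\n",
              x$call, x$delta_kda, x$threshold_kda))
  invisible(x)
}
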