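#' @keywords internal
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# Kyte-Doolittle hydropathy, used only to shape the synthetic default burial
# potential (hydrophobic residues prefer high neighbor counts).
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

# Engh-Huber-style ideal backbone geometry (lengths in Angstrom, angles in
# degrees); omega fixed trans.
BACKBONE_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.523, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180.0)

# Ideal (phi, psi) per SSE type.
IDEAL_DIHEDRALS <- list(
  helix  = c(phi = -60, psi = -40),
  strand = c(phi = -135, psi = 135))

#' Tunable scoring constants
#'
#' The functional forms of the low-resolution score terms are parameterized
#' by a small set of geometric constants; all are exposed here rather than
#' hard-coded so a run's configuration fully documents the potential.
#'
#' @param nc_lower,nc_upper bounds (Angstrom) of the cosine switching
#'   function used by the neighbor-count burial metric: a Cbeta pair counts
#'   1 below \code{nc_lower}, 0 above \code{nc_upper}.
#' @param loop_d_per_res maximum Euclidean span (Angstrom) a single loop
#'   residue can bridge in the loop-closure feasibility bound.
#' @param loop_d_offset additive offset (Angstrom) of that bound.
#' @param clash_radius Cbeta-Cbeta distance (Angstrom) below which residues
#'   from different SSEs are counted as clashing.
#' @param packing_cutoff axis-axis distance (Angstrom) beyond which the SSE
#'   packing term is zero.
#' @param rg_a,rg_b expected radius of gyration of an n-residue globule is
#'   \code{rg_a * n^(1/3) + rg_b} (Angstrom).
#' @param restraint_cap maximum penalty a single violated restraint can
#'   contribute (score units).
#' @param restraint_neutral penalty assigned to a restraint with an
#'   unplaced endpoint.
#' @param contact_upper default Cbeta upper bound (Angstrom) for contact
#'   restraints.
#' @param xl_tolerance tolerance (Angstrom) added to a cross-linker length
#'   to obtain the Calpha upper bound.
#' @param sse_radius_helix,sse_radius_strand bounding-cylinder radii
#'   (Angstrom) used by the SSE-SSE clash term.
#' @param potential_ceiling energy (in units of rt) assigned to bins never
#'   observed, so the Metropolis engine never sees non-finite scores.
#' @return a named list of class \code{score_constants}.
#' @export
score_constants <- function(nc_lower = 4.0, nc_upper = 11.4,
                            loop_d_per_res = 2.56, loop_d_offset = 2.0,
                            clash_radius = 3.0, packing_cutoff = 12.0,
                            rg_a = 2.5, rg_b = 0.0,
                            restraint_cap = 10.0, restraint_neutral = 1.0,
                            contact_upper = 8.0, xl_tolerance = 2.0,
                            sse_radius_helix = 2.3, sse_radius_strand = 1.9,
                            potential_ceiling = 5.0) {
  stopifnot(nc_lower < nc_upper, clash_radius > 0, packing_cutoff > 0)
  structure(list(
    nc_lower = nc_lower, nc_upper = nc_upper,
    loop_d_per_res = loop_d_per_res, loop_d_offset = loop_d_offset,
    clash_radius = clash_radius, packing_cutoff = packing_cutoff,
    rg_a = rg_a, rg_b = rg_b,
    restraint_cap = restraint_cap, restraint_neutral = restraint_neutral,
    contact_upper = contact_upper, xl_tolerance = xl_tolerance,
    sse_radius_helix = sse_radius_helix, sse_radius_strand = sse_radius_strand,
    potential_ceiling = potential_ceiling), class = "score_constants")
}
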