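# Single unit-conversion layer. Internal computations use micrometres,
# square micrometres, nanonewtons and nN/um^2 (= kPa); user-facing
# interfaces speak mm^2, mN and MPa. 1 mN = 1e6 nN; 1 mm^2 = 1e6 um^2;
# 1 MPa = 1e3 nN/um^2.

NN_PER_MN <- 1e6
UM2_PER_MM2 <- 1e6
KPA_PER_MPA <- 1e3

mn_to_nn <- function(x) x * NN_PER_MN
nn_to_mn <- function(x) x / NN_PER_MN
mm2_to_um2 <- function(x) x * UM2_PER_MM2
um2_to_mm2 <- function(x) x / UM2_PER_MM2
mpa_to_kpa <- function(x) x * KPA_PER_MPA
kpa_to_mpa <- function(x) x / KPA_PER_MPA

#' Shear stress implied by a friction force over a real contact area
#'
#' Friction force per unit real contact area, converted to MPa. With friction
#' in mN and area in square micrometres, `1 mN / 1 um^2 = 1e3 MPa`.
#'
#' @param friction_mN Friction force, mN.
#' @param area_um2 Real contact area, square micrometres.
#' @return Shear stress in MPa.
#' @keywords internal
shear_stress_mpa <- function(friction_mN, area_um2) {
  1e3 * friction_mN / area_um2
}

# Local, restorable RNG scope so every generator is a pure function of its
# seed without clobbering the caller's RNG stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
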