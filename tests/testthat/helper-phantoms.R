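# Shared fixtures, built once per test run. All inputs are generated in
# code; the closed-form ground truths live in the phantom generators.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

refPoiseuille <- function()
  fixture("poiseuille", poiseuillePhantom(radius = 10, length = 40,
                                          vmax = 60))

refTcpc <- function()
  fixture("tcpc", tcpcPhantom(splitIvcLpa = 0.75, splitSvcRpa = 0.9))

refTcpcSymmetric <- function()
  fixture("tcpcSym", tcpcPhantom())

# uniform axial flow in a straight tube (tube mask reused from a phantom)
uniformTubeField <- function(speed = 30) {
  ph <- refPoiseuille()
  d <- dim(ph@field@velocities)
  vel <- array(0, d)
  vel[, , , 3, ] <- speed
  velocityField4D(vel[, , , , 1, drop = FALSE], spacing = spacing(ph@field),
                  origin = gridOrigin(ph@field))
}

# rigid-rotation field v = omega x r about the z axis on a cubic grid
rotationField <- function(n = 41, omega = 2) {
  x <- seq(-(n - 1) / 2, (n - 1) / 2, by = 1)
  X <- array(rep(x, times = n * n), c(n, n, n))
  Y <- array(rep(rep(x, each = n), n), c(n, n, n))
  vel <- array(0, c(n, n, n, 3, 1))
  vel[, , , 1, 1] <- -omega * Y / 10        # cm/s for omega in rad/s, r in mm
  vel[, , , 2, 1] <- omega * X / 10
  org <- rep(min(x), 3)
  list(field = velocityField4D(vel, spacing = c(1, 1, 1), origin = org),
       mask = lumenMask(array(1L, c(n, n, n)), c(all = 1L),
                        spacing = c(1, 1, 1), origin = org))
}
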