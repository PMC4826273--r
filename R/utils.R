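## Internal numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
    n <- vnorm(v)
    if (n < 1e-12) stop("cannot normalize a zero-length vector")
    v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Rodrigues rotation matrix about unit axis by angle (radians).
rotationAboutAxis <- function(axis, angle) {
    u <- unitize(axis)
    c_ <- cos(angle); s_ <- sin(angle)
    ux <- matrix(c(0, u[3L], -u[2L],
                   -u[3L], 0, u[1L],
                   u[2L], -u[1L], 0), 3L, 3L)
    c_ * diag(3) + s_ * ux + (1 - c_) * tcrossprod(u)
}

## Signed angle (radians, (-pi, pi]) from a to b about unit axis n;
## a and b are assumed (close to) perpendicular to n.
signedAngleAbout <- function(a, b, n) {
    a <- unitize(a); b <- unitize(b); n <- unitize(n)
    s <- sum(n * pracmaCross(a, b))
    c_ <- sum(a * b)
    ang <- atan2(s, c_)
    if (ang <= -pi) ang <- ang + 2 * pi
    ang
}

pracmaCross <- function(a, b) {
    c(a[2L] * b[3L] - a[3L] * b[2L],
      a[3L] * b[1L] - a[1L] * b[3L],
      a[1L] * b[2L] - a[2L] * b[1L])
}

## Wrap an angle in degrees to (-180, 180].
wrapAngle <- function(x) {
    y <- (x + 180) %% 360 - 180
    ifelse(y <= -180, y + 360, y)
}

## Run expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
        set.seed(seed)
        on.exit({
            if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    force(expr)
}

## z-y-z Euler angles (degrees) of a rotation matrix R (columns = images of
## the base vectors). Returns c(alpha, beta, gamma) with
## R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma).
eulerZYZ <- function(R) {
    beta <- acos(max(-1, min(1, R[3L, 3L])))
    if (abs(sin(beta)) < 1e-10) {
        alpha <- atan2(R[2L, 1L], R[1L, 1L])
        gamma <- 0
    } else {
        alpha <- atan2(R[2L, 3L], R[1L, 3L])
        gamma <- atan2(R[3L, 2L], -R[3L, 1L])
    }
    rad2deg(c(alpha, beta, gamma))
}
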