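# Shared fixtures: everything is generated in code, nothing is stored.

default_bone <- function() elastic_constants()

small_volume_spec <- function(...) {
  volume_spec(shape = c(48L, 48L, 48L), noise_sd = 0, ...)
}

# isotropic stiffness in Lame form, the closed-form oracle for the
# transversely isotropic matrix in its isotropic limit
isotropic_stiffness_oracle <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  C[4, 4] <- C[5, 5] <- C[6, 6] <- mu
  C
}

# independent element-stiffness oracle: central-difference shape-function
# gradients and 3x3x3 Gauss quadrature, sharing no code with hex_stiffness()
hex_stiffness_oracle <- function(coords, C) {
  shape_vals <- function(xi) {
    s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
    (1 + s[, 1] * xi[1]) * (1 + s[, 2] * xi[2]) * (1 + s[, 3] * xi[3]) / 8
  }
  dshape_fd <- function(xi, h = 1e-6) {
    sapply(1:3, function(a) {
      e <- numeric(3); e[a] <- h
      (shape_vals(xi + e) - shape_vals(xi - e)) / (2 * h)
    })
  }
  g1 <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  w1 <- c(5, 8, 5) / 9
  ke <- matrix(0, 24, 24)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    xi <- c(g1[i], g1[j], g1[k])
    dN <- dshape_fd(xi)
    J <- t(dN) %*% coords
    dNdx <- dN %*% solve(t(J))
    B <- matrix(0, 6, 24)
    ix <- 3 * (1:8) - 2
    B[1, ix] <- dNdx[, 1]; B[2, ix + 1] <- dNdx[, 2]; B[3, ix + 2] <- dNdx[, 3]
    B[4, ix + 1] <- dNdx[, 3]; B[4, ix + 2] <- dNdx[, 2]
    B[5, ix] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 1]
    B[6, ix] <- dNdx[, 2]; B[6, ix + 1] <- dNdx[, 1]
    ke <- ke + t(B) %*% C %*% B * det(J) * w1[i] * w1[j] * w1[k]
  }
  ke
}

# random parallelepiped element (affine image of the reference cube)
random_parallelepiped <- function() {
  A <- diag(3) + matrix(runif(9, -0.2, 0.2), 3, 3)
  ref <- (hex_corner_signs_test() + 1) / 2
  ref %*% t(A)
}

hex_corner_signs_test <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
}
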