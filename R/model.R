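#' Uniform D weightings for a network
#'
#' D values partition each region's total input among its incoming
#' connections (region-to-region edges and latent inputs): they are
#' nonnegative and sum to 1 per region. D and B are not separately
#' identifiable from time series alone, so the fitting engine fixes D by
#' this uniform row-normalization: each of a region's incoming connections
#' receives an equal share `1 / indegree`.
#'
#' @param net A `bold_network`.
#' @return Named numeric vector over `connection_labels(net)`.
#' @export
uniform_D <- function(net) {
  labels <- connection_labels(net)
  tgt <- connection_targets(net)
  indeg <- table(tgt)
  D <- 1 / as.numeric(indeg[tgt])
  names(D) <- labels
  D
}

#' Build the signaling model matrices
#'
#' Lays parameter vectors out on the network topology: `M_input` holds D
#' values on region-to-region edges (`M_input[target, source] = D`),
#' `M_output` holds the DB products on the same edges, and the latent
#' blocks hold the D and DB entries of latent-input edges (regions by
#' latents). All matrices have zero diagonal (no self-loops).
#'
#' @param net A `bold_network`.
#' @param D,B Named numeric vectors over `connection_labels(net)` (edges
#'   and latent edges).
#' @return List with `M_input`, `M_output` (regions x regions),
#'   `Lat_D`, `Lat_DB` (regions x latents), `regions`, `latents`.
#' @export
build_matrices <- function(net, D, B) {
  labels <- connection_labels(net)
  abort_if(!all(labels %in% names(D)) || !all(labels %in% names(B)),
           "D and B must be named over the network's connection labels")
  D <- D[labels]; B <- B[labels]
  R <- length(net$regions)
  K <- nrow(net$latents)
  M_input <- matrix(0, R, R, dimnames = list(net$regions, net$regions))
  M_output <- M_input
  Lat_D <- matrix(0, R, max(K, 0),
                  dimnames = list(net$regions,
                                  if (K) net$latents$name else NULL))
  Lat_DB <- Lat_D
  ne <- nrow(net$edges)
  if (ne) {
    ti <- match(net$edges$to, net$regions)
    si <- match(net$edges$from, net$regions)
    for (e in seq_len(ne)) {
      M_input[ti[e], si[e]] <- D[e]
      M_output[ti[e], si[e]] <- D[e] * B[e]
    }
  }
  if (K) {
    lt <- match(net$latents$target, net$regions)
    for (l in seq_len(K)) {
      Lat_D[lt[l], l] <- D[ne + l]
      Lat_DB[lt[l], l] <- D[ne + l] * B[ne + l]
    }
  }
  list(M_input = M_input, M_output = M_output, Lat_D = Lat_D,
       Lat_DB = Lat_DB, regions = net$regions,
       latents = if (K) net$latents$name else character())
}

#' Solve the forward signaling model
#'
#' The output signaling of each region is the self-consistent fixed point
#' of the output equation driven by the latent inputs:
#' `S_output = (I - M_output)^{-1} (Lat_DB U)`. The region input signal --
#' the model's BOLD prediction -- is
#' `S_input = M_input S_output + Lat_D U`. The solve is exact (direct
#' linear solve, no iteration error) and requires the spectral radius of
#' `M_output` to be below 1 (a dissipative network).
#'
#' @param mats Matrix set from [build_matrices()].
#' @param latents Matrix, latents by time.
#' @return List with `S_output` and `S_input` (regions by time).
#' @export
solve_forward <- function(mats, latents) {
  rho <- spectral_radius(mats$M_output)
  abort_if(rho >= 1 - 1e-10,
           sprintf("cannot solve forward model: spectral radius %.4f >= 1", rho))
  R <- nrow(mats$M_output)
  drive <- mats$Lat_DB %*% latents
  S_output <- solve(diag(R) - mats$M_output, drive)
  S_input <- mats$M_input %*% S_output + mats$Lat_D %*% latents
  rownames(S_output) <- rownames(S_input) <- mats$regions
  list(S_output = S_output, S_input = S_input)
}

# Time-independent gain: S_input = forward_gain(mats) %*% latents.
forward_gain <- function(mats) {
  R <- nrow(mats$M_output)
  S <- solve(diag(R) - mats$M_output)
  G <- mats$M_input %*% S %*% mats$Lat_DB + mats$Lat_D
  rownames(G) <- mats$regions
  G
}
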