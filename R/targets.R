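#' Class target selection for the regression-style classifiers
#'
#' The binary problem is mapped to two scalar regression targets,
#' `T_Adeno = 0.85` and `T_Meso = 0.65`. On features normalized to the unit
#' interval, each target is required to be at least the grand mean of that
#' class's per-feature means; the additional separation requirement
#' `|T_Adeno - T_Meso| >= 0.5` is evaluated and reported but not enforced —
#' the chosen targets differ by only 0.2, so `separation_ok` is `FALSE`
#' with the standard values. A violated mean constraint attaches a warning
#' but the default targets are still returned.
#'
#' @param adeno_features,meso_features feature x subject matrices for the
#'   two classes, normalized to `[0, 1]` (see [scale_unit()]).
#' @param t_adeno,t_meso the target values (defaults 0.85 and 0.65).
#' @return A `target_map` list: `t_adeno`, `t_meso`, `adeno_ok`, `meso_ok`,
#'   `separation_ok`, and the two class grand means.
#' @export
select_targets <- function(adeno_features, meso_features,
                           t_adeno = 0.85, t_meso = 0.65) {
  adeno_features <- as.matrix(adeno_features)
  meso_features <- as.matrix(meso_features)
  mu_adeno <- mean(rowMeans(adeno_features))
  mu_meso <- mean(rowMeans(meso_features))
  adeno_ok <- mu_adeno <= t_adeno
  meso_ok <- mu_meso <= t_meso
  if (!adeno_ok || !meso_ok) {
    warning(sprintf(paste0("target constraint violated: class mean(s) exceed the ",
                           "targets (Adeno mean %.4f vs %.2f, Meso mean %.4f vs %.2f); ",
                           "defaults returned anyway"),
                    mu_adeno, t_adeno, mu_meso, t_meso))
  }
  structure(list(t_adeno = t_adeno, t_meso = t_meso,
                 adeno_ok = adeno_ok, meso_ok = meso_ok,
                 separation_ok = abs(t_adeno - t_meso) >= 0.5,
                 mean_adeno = mu_adeno, mean_meso = mu_meso),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("Class targets: T_Adeno = %.2f, T_Meso = %.2f\n",
              x$t_adeno, x$t_meso))
  cat(sprintf("  mean constraints: Adeno %s, Meso %s; separation >= 0.5: %s\n",
              x$adeno_ok, x$meso_ok, x$separation_ok))
  invisible(x)
}

# default targets without data-dependent checks (internal)
.default_targets <- function() {
  structure(list(t_adeno = 0.85, t_meso = 0.65,
                 adeno_ok = NA, meso_ok = NA, separation_ok = FALSE,
                 mean_adeno = NA_real_, mean_meso = NA_real_),
            class = "target_map")
}
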