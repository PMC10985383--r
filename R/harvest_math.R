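#' Theta-logistic maximum-sustainable-yield quantities
#'
#' Closed-form management quantities of the theta-logistic model
#' \deqn{N_{t+1} = N_t + N_t r_{max}\left[1 - (N_t/K)^\theta\right] - h_t N_t.}
#' The harvest *rate* that maximises sustainable yield is
#' \deqn{h_{MSY} = r_{max}\,\theta/(\theta+1),}
#' the corresponding equilibrium population is
#' \deqn{N_{MSY} = K\,(\theta+1)^{-1/\theta},}
#' and the yield itself is \eqn{H_{MSY} = h_{MSY} N_{MSY}
#' = r_{max} K \theta / (\theta+1)^{(\theta+1)/\theta}}.
#' With linear density dependence (\eqn{\theta = 1}) these reduce to the
#' familiar \eqn{r_{max}/2}, \eqn{K/2} and \eqn{r_{max}K/4}.
#'
#' @param rmax Intrinsic (maximum) net annual growth rate, >= 0.
#' @param theta Density-dependence shape, > 0 (1 = linear, > 1 concave,
#'   < 1 convex).
#' @param K Carrying capacity, > 0 (individuals).
#' @return `h_msy`: rate in `[0, rmax)`; `n_msy`: individuals in
#'   `(K/e, K)`; `yield_msy`: individuals per year.
#' @examples
#' h_msy(0.12, 2.51)
#' n_msy(1000, 1)      # K/2
#' yield_msy(0.2, 1000, 1)  # rmax K / 4
#' @export
h_msy <- function(rmax, theta) {
  check_rmax(rmax); check_theta(theta)
  rmax * theta / (theta + 1)
}

#' @rdname h_msy
#' @export
n_msy <- function(K, theta) {
  check_K(K); check_theta(theta)
  K * (theta + 1)^(-1 / theta)
}

#' @rdname h_msy
#' @export
yield_msy <- function(rmax, K, theta) {
  check_rmax(rmax); check_K(K); check_theta(theta)
  rmax * K * theta / (theta + 1)^((theta + 1) / theta)
}

#' Allowable-take rules: PTL, PEG and PBR
#'
#' The three allowable-take rules implemented here share the logic "population
#' size times a sustainable rate times a policy factor" but differ in the
#' population model behind the rate and in how policy and science are
#' separated:
#' \describe{
#'   \item{PTL (potential take level)}{\eqn{F_{obj}\, r_{max}\theta/(\theta+1)
#'     \, N_t} on the theta-logistic model; `Fobj = 1` targets MSY, values
#'     below 1 are precautionary, values above 1 (up to \eqn{(\theta+1)/\theta},
#'     the extinction boundary) aim at population reduction.}
#'   \item{PEG (potential excess growth)}{\eqn{N \beta (\lambda_{max}-1)} with
#'     safety factor \eqn{\beta = F_s \le 0.5} (0.5 is a strict maximum,
#'     equivalent to MSY under linear density dependence).}
#'   \item{PBR (potential biological removal)}{\eqn{N_{min}\,(R_{max}/2)\,F_r}
#'     with recovery factor \eqn{F_r \in (0, 1]} and a *minimum* population
#'     estimate.}
#' }
#' The rules coincide where their assumptions do: `ptl(N, r, 1, 1)`,
#' `peg(N, 1 + r, 0.5)` and `pbr(N, r, 1)` are identical.
#'
#' @param N,Nmin Population size / minimum population estimate (individuals,
#'   >= 0).
#' @param rmax,Rmax Intrinsic net annual growth rate (>= 0).
#' @param theta Density-dependence shape (> 0).
#' @param Fobj PTL management-objective factor in `[0, (theta+1)/theta)`.
#' @param lambda_max Intrinsic finite growth rate (`rmax + 1`).
#' @param Fs PEG safety factor in `(0, 0.5]`.
#' @param Fr PBR recovery factor in `(0, 1]`.
#' @return Allowable take, individuals per year.
#' @examples
#' ptl(91190, 0.12, 1, 1)
#' peg(10000, 1.2, 0.5)
#' pbr(1000, 0.2, 0.1)
#' @export
ptl <- function(N, rmax, theta, Fobj) {
  check_N(N); check_rmax(rmax); check_theta(theta)
  if (any(!is.finite(Fobj)) || any(Fobj < 0) || any(Fobj >= (theta + 1) / theta))
    stop("Fobj must lie in [0, (theta+1)/theta)", call. = FALSE)
  Fobj * h_msy(rmax, theta) * N
}

#' @rdname ptl
#' @export
peg <- function(N, lambda_max, Fs) {
  check_N(N)
  if (any(!is.finite(lambda_max)) || any(lambda_max < 0))
    stop("lambda_max must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(Fs)) || any(Fs <= 0) || any(Fs > 0.5))
    stop("Fs must lie in (0, 0.5]; 0.5 is a strict maximum", call. = FALSE)
  N * Fs * (lambda_max - 1)
}

#' @rdname ptl
#' @export
pbr <- function(Nmin, Rmax, Fr) {
  check_N(Nmin); check_rmax(Rmax)
  if (any(!is.finite(Fr)) || any(Fr <= 0) || any(Fr > 1))
    stop("Fr must lie in (0, 1]", call. = FALSE)
  Nmin * (Rmax / 2) * Fr
}

#' Map between the objective factor and the proportion of MSY taken
#'
#' Taking only a proportion `pobj` of the maximum sustainable yield is a
#' common way to state a precautionary objective. At equilibrium the
#' theta-logistic links the two by
#' \deqn{p_{obj} = F_{obj}\left[1 + \theta(1 - F_{obj})\right]^{1/\theta},}
#' which `pobj_from_fobj` evaluates and `fobj_from_pobj` inverts numerically
#' on the sub-MSY branch \eqn{F_{obj} \in (0, 1]} (the branch whose harvested
#' equilibrium sits above \eqn{N_{MSY}} and is dynamically stable). The
#' relation also has an upper root \eqn{F_{obj} > 1} whose equilibrium is
#' below \eqn{N_{MSY}} and unstable; set `branch = "upper"` to explore it.
#'
#' @param Fobj Objective factor in `(0, (theta+1)/theta)`.
#' @param pobj Desired proportion of MSY, in `(0, 1]`.
#' @param theta Density-dependence shape (> 0).
#' @param branch `"lower"` (default, `Fobj <= 1`) or `"upper"`.
#' @param tol Relative root-finding tolerance.
#' @return `pobj_from_fobj`: proportion in `(0, 1]`; `fobj_from_pobj`: the
#'   objective factor on the requested branch.
#' @examples
#' fobj_from_pobj(0.5, 2.20)   # ~0.33: take half the MSY
#' pobj_from_fobj(1, 3)        # MSY itself
#' @export
pobj_from_fobj <- function(Fobj, theta) {
  check_theta(theta)
  if (any(!is.finite(Fobj)) || any(Fobj <= 0) || any(Fobj >= (theta + 1) / theta))
    stop("Fobj must lie in (0, (theta+1)/theta)", call. = FALSE)
  Fobj * (1 + theta * (1 - Fobj))^(1 / theta)
}

#' @rdname pobj_from_fobj
#' @export
fobj_from_pobj <- function(pobj, theta, branch = c("lower", "upper"), tol = 1e-10) {
  branch <- match.arg(branch)
  check_theta(theta)
  if (!is.numeric(pobj) || length(pobj) != 1L || !is.finite(pobj) ||
      pobj <= 0 || pobj > 1)
    stop("pobj must lie in (0, 1]", call. = FALSE)
  if (pobj == 1) return(1)
  f <- function(F) pobj_from_fobj(F, theta) - pobj
  interval <- if (branch == "lower") c(1e-12, 1) else
    c(1, (theta + 1) / theta - 1e-12)
  root <- stats::uniroot(f, interval = interval, tol = tol * max(1, abs(interval[2])))
  root$root
}

#' Equilibrium population fraction under a PTL objective
#'
#' The stable harvested equilibrium, as a fraction of carrying capacity,
#' implied by objective factor `Fobj` on the theta-logistic model:
#' \deqn{N^*/K = \left[1 - F_{obj}\,\theta/(\theta+1)\right]^{1/\theta}.}
#' `Fobj = 0` leaves the population at `K`; `Fobj = 1` at \eqn{N_{MSY}};
#' the boundary \eqn{F_{obj} = (\theta+1)/\theta} drives it to extinction.
#'
#' @inheritParams pobj_from_fobj
#' @return Fraction of `K` in `(0, 1]`.
#' @export
equilibrium_fraction <- function(Fobj, theta) {
  check_theta(theta)
  if (any(!is.finite(Fobj)) || any(Fobj < 0) || any(Fobj >= (theta + 1) / theta))
    stop("Fobj must lie in [0, (theta+1)/theta): beyond is the extinction boundary",
         call. = FALSE)
  (1 - Fobj * theta / (theta + 1))^(1 / theta)
}

#' Convert a pre-breeding harvest rate to a post-breeding basis
#'
#' Allowable-take rates are derived for a population censused before
#' breeding. A post-breeding survey also counts the young of the year, so
#' the same absolute take corresponds to the smaller rate
#' \deqn{h_{post} = h_{pre} / (1 + h_{pre}).}
#' Applied to the PTL rate \eqn{h = F_{obj} r_{max}\theta/(\theta+1)} this
#' gives \eqn{F_{obj} r_{max}\theta/[(\theta+1) + F_{obj} r_{max}\theta]}.
#'
#' @param h_pre Pre-breeding harvest rate(s) in `[0, 1)`.
#' @return Post-breeding rate(s); strictly below `h_pre` for positive rates
#'   and bounded above by 0.5.
#' @examples
#' h_post_breeding(0.30)  # 0.23
#' @export
h_post_breeding <- function(h_pre) {
  if (any(!is.finite(h_pre)) || any(h_pre < 0) || any(h_pre >= 1))
    stop("h_pre must lie in [0, 1)", call. = FALSE)
  h_pre / (1 + h_pre)
}

#' Inflate retrieved harvest for crippling loss
#'
#' Reported offtake counts retrieved birds only; birds struck but not
#' retrieved ("crippling loss") die as well. A crippling rate `c` inflates
#' the retrieved harvest to total offtake `retrieved * (1 + c)`. For North
#' American ducks 0.20 is conventional.
#'
#' @param retrieved_harvest Retrieved harvest (>= 0, individuals).
#' @param crippling_rate Unretrieved fraction relative to retrieved (>= 0).
#' @return Total offtake, individuals.
#' @examples
#' adjust_for_crippling(100, 0.20)  # 120
#' @export
adjust_for_crippling <- function(retrieved_harvest, crippling_rate) {
  if (any(!is.finite(retrieved_harvest)) || any(retrieved_harvest < 0))
    stop("retrieved_harvest must be >= 0", call. = FALSE)
  if (any(!is.finite(crippling_rate)) || any(crippling_rate < 0))
    stop("crippling_rate must be >= 0", call. = FALSE)
  retrieved_harvest * (1 + crippling_rate)
}

check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("theta must be finite and > 0 (theta = 0 is undefined)", call. = FALSE)
  invisible(NULL)
}
check_rmax <- function(rmax) {
  if (any(!is.finite(rmax)) || any(rmax < 0))
    stop("rmax must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}
check_K <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("K must be finite and > 0", call. = FALSE)
  invisible(NULL)
}
check_N <- function(N) {
  if (any(!is.finite(N)) || any(N < 0))
    stop("population size must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}
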