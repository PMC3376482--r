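#' Dichotomous airway tree
#'
#' The bronchial tree is dichotomous: each airway of generation `j` splits
#' into two airways of generation `j + 1`, so generation `j` holds `2^j`
#' airways and `n` generations feed `2^n` terminal compartments. Resistances
#' are given per airway as a list `resistances[[j + 1]][k]` (cmH2O s/l) for
#' generation `j = 0..n`, airway `k = 1..2^j`.
#'
#' @param n number of generations (integer >= 0).
#' @param resistances list of length `n + 1`; element `j + 1` is a numeric
#'   vector of length `2^j` of strictly positive resistances. A single number
#'   is recycled within its generation.
#' @return an object of class `airway_tree`.
#' @examples
#' airway_tree(1, list(1.0, c(1.0, 1.0)))
#' @export
airway_tree <- function(n, resistances) {
  n <- as.integer(n)
  if (n < 0) stop("airway_tree: n must be >= 0")
  if (length(resistances) != n + 1L)
    stop("airway_tree: resistances must have one element per generation 0..n (",
         n + 1L, " needed, got ", length(resistances), ")")
  resistances <- lapply(seq_len(n + 1L), function(g) {
    r <- resistances[[g]]
    if (length(r) == 1L) r <- rep(r, 2^(g - 1L))
    if (length(r) != 2^(g - 1L))
      stop("airway_tree: generation ", g - 1L, " needs ", 2^(g - 1L),
           " resistances, got ", length(r))
    if (any(!is.finite(r)) || any(r <= 0))
      stop("airway_tree: all resistances must be finite and strictly positive ",
           "(generation ", g - 1L, ")")
    as.numeric(r)
  })
  structure(list(n = n, resistances = resistances), class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf("<airway_tree> %d generation(s), %d airway(s), %d compartment(s)\n",
              x$n, 2^(x$n + 1) - 1, 2^x$n))
  invisible(x)
}

# uniform scaling (used for the expiratory-resistance factor)
scale_tree <- function(tree, factor) {
  airway_tree(tree$n, lapply(tree$resistances, function(r) r * factor))
}

#' Airway path serving a compartment
#'
#' Indices `k_j` of the airway in each generation `j = 0..n` on the path from
#' the root to terminal compartment `i`, by the floor recursion
#' `k_n = i`, `k_j = floor((k_{j+1} - 1)/2) + 1`.
#'
#' @param i compartment index in `1..2^n`.
#' @param n number of generations.
#' @return integer vector `c(k_0, ..., k_n)` of length `n + 1`.
#' @examples
#' path_indices(3, 2)  # root -> second airway of generation 1 -> airway 3
#' @export
path_indices <- function(i, n) {
  n <- as.integer(n); i <- as.integer(i)
  if (i < 1L || i > 2^n) stop("path_indices: i must be in 1..2^n, got ", i)
  k <- integer(n + 1L)
  k[n + 1L] <- i
  for (j in seq_len(n)) # fills k_{n-1} .. k_0
    k[n + 1L - j] <- (k[n + 2L - j] - 1L) %/% 2L + 1L
  k
}

#' Compartment-membership indicator of an airway
#'
#' The 0/1 vector `Z[j,k]` of length `2^n` whose `l`-th element is 1 exactly
#' when terminal compartment `l` is ventilated through airway `k` of
#' generation `j`, i.e. `l` in `(k-1)*2^(n-j)+1 .. k*2^(n-j)`.
#'
#' @param j generation, `0..n`.
#' @param k airway index within the generation, `1..2^j`.
#' @param n number of generations.
#' @return numeric 0/1 vector of length `2^n`.
#' @export
structure_vector <- function(j, k, n) {
  if (j < 0 || j > n) stop("structure_vector: j must be in 0..n, got ", j)
  if (k < 1 || k > 2^j) stop("structure_vector: k must be in 1..2^j, got ", k)
  z <- numeric(2^n)
  z[((k - 1) * 2^(n - j) + 1):(k * 2^(n - j))] <- 1
  z
}

#' Assemble the resistance matrix of an airway tree
#'
#' `R = sum_j sum_k R[j,k] * Z[j,k] %*% t(Z[j,k])`: entry `(i, i')` is the
#' total resistance of the airway path shared by compartments `i` and `i'`.
#' The result is symmetric positive definite for any strictly positive
#' resistance table.
#'
#' @param tree an [airway_tree()].
#' @return a `2^n x 2^n` numeric matrix (cmH2O s/l).
#' @export
resistance_matrix <- function(tree) {
  m <- 2^tree$n
  R <- matrix(0, m, m)
  for (j in 0:tree$n) {
    for (k in seq_len(2^j)) {
      z <- structure_vector(j, k, tree$n)
      R <- R + tree$resistances[[j + 1L]][k] * tcrossprod(z)
    }
  }
  R
}
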