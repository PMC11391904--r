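## Reverse-mode automatic differentiation on dense matrices.
##
## Every node holds an eagerly computed matrix value, its parents, and one
## vector-Jacobian-product closure per differentiable parent. The VJP
## closures build new graph nodes from the same primitives, so gradients
## are themselves differentiable: forces (-dE/dR) and virtual-derivative
## couplings enter the training loss and are differentiated again with
## respect to the network parameters.
##
## Broadcasting follows a restricted numpy convention: operands of equal
## shape, or one of (1 x 1), (n x 1), (1 x k) against (n x k).

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0

ag_new <- function(value, parents = list(), vjps = list()) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjps <- vjps
  id <- .ag_env$counter + 1
  .ag_env$counter <- id
  e$id <- id
  tr <- FALSE
  for (p in parents) if (p$track) { tr <- TRUE; break }
  e$track <- tr
  class(e) <- "ag_node"
  e
}

#' Create an autodiff leaf node
#'
#' @param value numeric matrix (vectors are treated as column matrices).
#' @param track if `TRUE`, gradients with respect to this leaf are
#'   computed by [ag_grad()].
#' @return an `ag_node`.
#' @keywords internal
ag_leaf <- function(value, track = FALSE) {
  n <- ag_new(as_mat(value))
  n$track <- isTRUE(track)
  n
}

ag_const <- function(value) ag_leaf(value, track = FALSE)

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else as_mat(x)

bc_expand <- function(v, d) {
  dv <- dim(v)
  if (dv[1] == d[1] && dv[2] == d[2]) return(v)
  if (dv[1] == 1L && dv[2] == 1L) return(matrix(v[1], d[1], d[2]))
  if (dv[1] == d[1] && dv[2] == 1L) return(matrix(v, d[1], d[2]))
  if (dv[1] == 1L && dv[2] == d[2]) {
    return(matrix(rep(v, each = d[1]), d[1], d[2]))
  }
  stop("non-broadcastable shapes: ", paste(dv, collapse = "x"), " vs ",
       paste(d, collapse = "x"))
}

## apply an elementwise binary op with cheap recycling where possible
op_bc <- function(op, av, bv) {
  da <- dim(av); db <- dim(bv)
  if (da[1] == db[1] && da[2] == db[2]) return(op(av, bv))
  d <- c(max(da[1], db[1]), max(da[2], db[2]))
  if (da[1] == d[1] && da[2] == d[2]) {
    if (db[1] == 1L && db[2] == 1L) return(op(av, bv[1]))
    if (db[2] == 1L && db[1] == d[1]) return(op(av, as.numeric(bv)))
    return(op(av, bc_expand(bv, d)))
  }
  if (db[1] == d[1] && db[2] == d[2]) {
    if (da[1] == 1L && da[2] == 1L) return(op(av[1], bv))
    if (da[2] == 1L && da[1] == d[1]) {
      r <- op(as.numeric(av), bv)
      return(r)
    }
    return(op(bc_expand(av, d), bv))
  }
  op(bc_expand(av, d), bc_expand(bv, d))
}

bc_dim <- function(da, db) {
  if (da[1] == db[1] && da[2] == db[2]) return(da)
  c(max(da[1], db[1]), max(da[2], db[2]))
}

## reduce a gradient node g (shape dfrom) back to shape dto by summation
ag_reduce_to <- function(g, dto) {
  dfrom <- dim(g$value)
  if (identical(dfrom, dto)) return(g)
  if (all(dto == 1L)) return(ag_sum_all(g))
  if (dto[1] == dfrom[1] && dto[2] == 1L) return(ag_sumcols(g))
  if (dto[1] == 1L && dto[2] == dfrom[2]) return(ag_sumrows(g))
  stop("cannot reduce gradient from ", paste(dfrom, collapse = "x"),
       " to ", paste(dto, collapse = "x"))
}

ag_add <- function(a, b) {
  if (!inherits(a, "ag_node")) a <- ag_const(a)
  if (!inherits(b, "ag_node")) b <- ag_const(b)
  ag_new(op_bc(`+`, a$value, b$value), list(a, b),
         list(function(g) ag_reduce_to(g, dim(a$value)),
              function(g) ag_reduce_to(g, dim(b$value))))
}

ag_sub <- function(a, b) {
  if (!inherits(a, "ag_node")) a <- ag_const(a)
  if (!inherits(b, "ag_node")) b <- ag_const(b)
  ag_new(op_bc(`-`, a$value, b$value), list(a, b),
         list(function(g) ag_reduce_to(g, dim(a$value)),
              function(g) ag_reduce_to(ag_neg(g), dim(b$value))))
}

ag_mul <- function(a, b) {
  if (!inherits(a, "ag_node")) a <- ag_const(a)
  if (!inherits(b, "ag_node")) b <- ag_const(b)
  ag_new(op_bc(`*`, a$value, b$value), list(a, b),
         list(function(g) ag_reduce_to(ag_mul(g, b), dim(a$value)),
              function(g) ag_reduce_to(ag_mul(g, a), dim(b$value))))
}

ag_div <- function(a, b) {
  if (!inherits(a, "ag_node")) a <- ag_const(a)
  if (!inherits(b, "ag_node")) b <- ag_const(b)
  out <- ag_new(op_bc(`/`, a$value, b$value), list(a, b), list(NULL, NULL))
  out$vjps <- list(
    function(g) ag_reduce_to(ag_div(g, b), dim(a$value)),
    function(g) ag_reduce_to(ag_neg(ag_mul(g, ag_div(out, b))),
                             dim(b$value)))
  out
}

ag_neg <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  ag_new(-a$value, list(a), list(function(g) ag_neg(g)))
}

ag_matmul <- function(a, b) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  b <- if (inherits(b, "ag_node")) b else ag_const(b)
  ag_new(a$value %*% b$value, list(a, b),
         list(function(g) ag_matmul(g, ag_t(b)),
              function(g) ag_matmul(ag_t(a), g)))
}

ag_t <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  ag_new(t(a$value), list(a), list(function(g) ag_t(g)))
}

ag_rowgather <- function(a, idx) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  n <- nrow(a$value)
  ag_new(a$value[idx, , drop = FALSE], list(a),
         list(function(g) ag_rowscatter(g, idx, n)))
}

ag_rowscatter <- function(a, idx, n) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  v <- matrix(0, n, ncol(a$value))
  rs <- rowsum(a$value, group = idx)
  v[as.integer(rownames(rs)), ] <- rs
  ag_new(v, list(a), list(function(g) ag_rowgather(g, idx)))
}

ag_colgather <- function(a, cols) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  k <- ncol(a$value)
  ag_new(a$value[, cols, drop = FALSE], list(a),
         list(function(g) ag_colscatter(g, cols, k)))
}

ag_colscatter <- function(a, cols, k) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  v <- matrix(0, nrow(a$value), k)
  if (anyDuplicated(cols)) {
    for (q in seq_along(cols)) v[, cols[q]] <- v[, cols[q]] + a$value[, q]
  } else {
    v[, cols] <- a$value
  }
  ag_new(v, list(a), list(function(g) ag_colgather(g, cols)))
}

ag_sum_all <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  d <- dim(a$value)
  ag_new(matrix(sum(a$value), 1, 1), list(a),
         list(function(g) ag_mul(ag_const(matrix(1, d[1], d[2])), g)))
}

ag_sumrows <- function(a) {  # n x k -> 1 x k
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  d <- dim(a$value)
  ag_new(matrix(colSums(a$value), 1, d[2]), list(a),
         list(function(g) ag_mul(ag_const(matrix(1, d[1], d[2])), g)))
}

ag_sumcols <- function(a) {  # n x k -> n x 1
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  d <- dim(a$value)
  ag_new(matrix(rowSums(a$value), d[1], 1), list(a),
         list(function(g) ag_mul(ag_const(matrix(1, d[1], d[2])), g)))
}

ag_exp <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  out <- ag_new(exp(a$value), list(a), list(NULL))
  out$vjps[[1]] <- function(g) ag_mul(g, out)
  out
}

ag_sqrt <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  out <- ag_new(sqrt(a$value), list(a), list(NULL))
  out$vjps[[1]] <- function(g) ag_div(ag_mul(g, ag_const(matrix(0.5, 1, 1))), out)
  out
}

ag_sigmoid <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  out <- ag_new(1 / (1 + exp(-a$value)), list(a), list(NULL))
  out$vjps[[1]] <- function(g) {
    ag_mul(ag_mul(g, out), ag_sub(ag_const(matrix(1, 1, 1)), out))
  }
  out
}

## shifted softplus log(1 + e^x) - log(2); smooth, ssp(0) = 0
ag_ssp <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  x <- a$value
  v <- pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
  ag_new(v, list(a), list(function(g) ag_mul(g, ag_sigmoid(a))))
}

ag_sin <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  ag_new(sin(a$value), list(a), list(function(g) ag_mul(g, ag_cos(a))))
}

ag_cos <- function(a) {
  a <- if (inherits(a, "ag_node")) a else ag_const(a)
  ag_new(cos(a$value), list(a), list(function(g) ag_neg(ag_mul(g, ag_sin(a)))))
}

ag_square <- function(a) ag_mul(a, a)

## column-bind a list of nodes
ag_cbind <- function(parts) {
  ks <- vapply(parts, function(p) ncol(ag_value(p)), integer(1))
  ktot <- sum(ks)
  off <- cumsum(c(0L, ks))
  out <- NULL
  for (i in seq_along(parts)) {
    piece <- ag_colscatter(parts[[i]], off[i] + seq_len(ks[i]), ktot)
    out <- if (is.null(out)) piece else ag_add(out, piece)
  }
  out
}

#' Gradients of a graph output with respect to leaf nodes
#'
#' Runs reverse accumulation from `root`. The returned gradients are graph
#' nodes themselves and may be differentiated again.
#'
#' @param root output node (any shape; `seed` defaults to ones).
#' @param wrt list of nodes to differentiate with respect to.
#' @param seed optional seed matrix/node with the shape of `root`.
#' @return list of gradient nodes matching `wrt`.
#' @keywords internal
ag_grad <- function(root, wrt, seed = NULL) {
  if (inherits(wrt, "ag_node")) wrt <- list(wrt)
  seed <- if (is.null(seed)) {
    ag_const(matrix(1, nrow(root$value), ncol(root$value)))
  } else if (inherits(seed, "ag_node")) seed else ag_const(seed)

  ## collect reachable tracked nodes; parents always have smaller ids than
  ## children, so decreasing id order is a valid reverse topological order
  nodes <- vector("list", 1024); nn <- 0L
  stack <- vector("list", 256); sp <- 1L
  stack[[1L]] <- root
  while (sp > 0L) {
    nd <- stack[[sp]]; sp <- sp - 1L
    if (!is.null(nd$.seen)) next
    nd$.seen <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) {
      if (p$track && is.null(p$.seen)) {
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(x) x$id, numeric(1)), decreasing = TRUE)
  nodes <- nodes[ord]

  root$.g <- seed
  for (nd in nodes) {
    g <- nd$.g
    if (is.null(g)) next
    prt <- nd$parents
    for (k in seq_along(prt)) {
      p <- prt[[k]]
      if (!p$track) next
      contrib <- nd$vjps[[k]](g)
      p$.g <- if (is.null(p$.g)) contrib else ag_add(p$.g, contrib)
    }
  }
  out <- lapply(wrt, function(w) {
    g <- w$.g
    if (is.null(g)) ag_const(matrix(0, nrow(w$value), ncol(w$value))) else g
  })
  for (nd in nodes) { nd$.g <- NULL; nd$.seen <- NULL }
  out
}
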