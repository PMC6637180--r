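#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Gaussian elastic net by cyclic coordinate descent with warm starts along a
// decreasing lambda path.  Inputs are expected pre-processed by the R wrapper:
// columns of X centered (and, when standardize = TRUE upstream, scaled to unit
// population variance), y centered.  Solves, for each lambda[l],
//
//   min_b (1/(2n)) * sum_i (y_i - x_i b)^2
//         + lambda * ( alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2 )
//
// The residual r = y - X b is maintained throughout.  After each full sweep
// the algorithm iterates on the active set (nonzero coefficients) until
// converged, then re-checks all predictors; convergence is declared when a
// full sweep moves no coefficient enough that v_j * (delta b_j)^2 exceeds
// eps (the caller scales eps by the null deviance, the usual relative
// convergence threshold for coordinate descent).
static inline double soft_threshold(double z, double g) {
    if (z > g) return z - g;
    if (z < -g) return z + g;
    return 0.0;
}

// [[Rcpp::export]]
List enet_path_cd(const NumericMatrix& X, const NumericVector& y,
                  double alpha, const NumericVector& lambda,
                  double eps, int max_iter) {
    const int n = X.nrow(), p = X.ncol(), nlam = lambda.size();
    NumericMatrix beta(p, nlam);
    IntegerVector iters(nlam);
    std::vector<double> b(p, 0.0), r(y.begin(), y.end()), v(p);
    const double* xp = X.begin();

    for (int j = 0; j < p; ++j) {
        const double* xj = xp + (size_t)j * n;
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
        v[j] = s / n;
    }

    std::vector<int> active;
    active.reserve(p);

    for (int l = 0; l < nlam; ++l) {
        const double l1 = lambda[l] * alpha;
        const double l2 = lambda[l] * (1.0 - alpha);
        int sweeps = 0;
        bool converged = false;
        while (!converged) {
            // full sweep over all predictors
            double maxd = 0.0;
            active.clear();
            for (int j = 0; j < p; ++j) {
                if (v[j] <= 0.0) continue;
                const double* xj = xp + (size_t)j * n;
                double dot = 0.0;
                for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
                const double z = dot / n + v[j] * b[j];
                const double bnew = soft_threshold(z, l1) / (v[j] + l2);
                const double d = bnew - b[j];
                if (d != 0.0) {
                    for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
                    b[j] = bnew;
                    const double sc = v[j] * d * d;
                    if (sc > maxd) maxd = sc;
                }
                if (b[j] != 0.0) active.push_back(j);
            }
            if (++sweeps >= max_iter)
                stop("coordinate descent did not converge within %d sweeps (lambda index %d)",
                     max_iter, l + 1);
            if (maxd < eps) { converged = true; break; }
            // inner sweeps restricted to the active set
            while (true) {
                double maxda = 0.0;
                for (int k = 0; k < (int)active.size(); ++k) {
                    const int j = active[k];
                    const double* xj = xp + (size_t)j * n;
                    double dot = 0.0;
                    for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
                    const double z = dot / n + v[j] * b[j];
                    const double bnew = soft_threshold(z, l1) / (v[j] + l2);
                    const double d = bnew - b[j];
                    if (d != 0.0) {
                        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
                        b[j] = bnew;
                        const double sc = v[j] * d * d;
                        if (sc > maxda) maxda = sc;
                    }
                }
                if (++sweeps >= max_iter)
                    stop("coordinate descent did not converge within %d sweeps (lambda index %d)",
                         max_iter, l + 1);
                if (maxda < eps) break;
            }
        }
        iters[l] = sweeps;
        for (int j = 0; j < p; ++j) beta(j, l) = b[j];
    }
    return List::create(_["beta"] = beta, _["iterations"] = iters);
}
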