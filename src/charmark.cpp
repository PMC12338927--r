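#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Power iteration for the left fixed point pi = pi P of a row-stochastic
// matrix, started from the uniform vector.  Stops when the L1 change
// between successive iterates drops below tol.  Returns the (unnormalised
// beyond numerical drift) iterate, the achieved infinity-norm residual of
// pi P - pi, and the iteration count; validation and the clip/renormalise
// step live on the R side.
// [[Rcpp::export(name = ".stationary_power_cpp")]]
List stationary_power_cpp(NumericMatrix P, double tol, int maxIter) {
    const int k = P.nrow();
    std::vector<double> pi(k, 1.0 / k), nxt(k);
    int it = 0;
    for (it = 0; it < maxIter; ++it) {
        for (int j = 0; j < k; ++j) {
            double s = 0.0;
            for (int i = 0; i < k; ++i) s += pi[i] * P(i, j);
            nxt[j] = s;
        }
        double delta = 0.0;
        for (int j = 0; j < k; ++j) delta += std::fabs(nxt[j] - pi[j]);
        pi = nxt;
        if (delta < tol) { ++it; break; }
    }
    double res = 0.0;
    for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int i = 0; i < k; ++i) s += pi[i] * P(i, j);
        double d = std::fabs(s - pi[j]);
        if (d > res) res = d;
    }
    return List::create(_["pi"] = NumericVector(pi.begin(), pi.end()),
                        _["residual"] = res,
                        _["iterations"] = it);
}

// Sample a Markov chain path of the requested length.  cumP holds row-wise
// cumulative transition probabilities; init is the 1-based initial state;
// u is a vector of length >= len of iid U(0,1) draws taken from R's RNG so
// that set.seed() governs the whole simulation (u[0] is unused here: the
// caller spends it on the initial state).
// [[Rcpp::export(name = ".sample_chain_cpp")]]
IntegerVector sample_chain_cpp(NumericMatrix cumP, int init, int len,
                               NumericVector u) {
    const int k = cumP.ncol();
    IntegerVector out(len);
    out[0] = init;
    int cur = init - 1;
    for (int t = 1; t < len; ++t) {
        const double x = u[t];
        int j = 0;
        while (j < k - 1 && x > cumP(cur, j)) ++j;
        out[t] = j + 1;
        cur = j;
    }
    return out;
}
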