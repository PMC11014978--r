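#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based per-trajectory RNG (splitmix64). Each trajectory gets an
// independent stream keyed by (master seed, trajectory index), so ensembles
// are reproducible, order-independent, and usable as common random numbers
// across objective evaluations during model fitting.
static inline uint64_t sm64_next(uint64_t &state) {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

static inline uint64_t stream_key(uint64_t seed, uint64_t idx) {
    // hash the (seed, idx) pair once so streams start at scattered states
    uint64_t s = seed * 0xD1B54A32D192ED03ULL + idx * 0x8CB92BA72F3D8DD7ULL;
    uint64_t k = sm64_next(s);
    return k;
}

static inline double runif01(uint64_t &state) {
    // uniform in (0, 1); never exactly 0 or 1
    return ((sm64_next(state) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Six-state transit walk, discrete time. States: 1 pre-encounter, 2 at the
// roadblock, 3 backtracked, 5 ramming position (dislodging attempt), 6 past
// the roadblock. State 4 (roadblock dissociated) is folded into the
// roadblock on/off flag, as in the discrete-time update rules.
struct TransitResult {
    double duration;
    bool transited;
    int n_cycles;
    bool dislodged;
};

static TransitResult transit_one(double p_off, double p_bt, double p_rec,
                                 double p1, double dt, double t_max,
                                 uint64_t rng_state) {
    int state = 1;
    bool rb_on = true;
    double t_c = 0.0;
    int n_cycles = 0;
    bool dislodged = false;

    while (state != 6 && t_c < t_max) {
        if (rb_on && runif01(rng_state) < p_off) rb_on = false;
        switch (state) {
        case 1:
            state = 5;
            break;
        case 2:
            if (rb_on) {
                if (runif01(rng_state) < p_bt) state = 3;
            } else {
                state = 6;
            }
            break;
        case 3:
            if (runif01(rng_state) < p_rec) {
                state = 5;
                ++n_cycles;
            }
            break;
        case 5:
            if (rb_on) {
                if (runif01(rng_state) < p1) {
                    state = 6;
                    dislodged = true;
                } else {
                    state = 2;
                }
            } else {
                state = 6;
            }
            break;
        }
        t_c += dt;
    }

    TransitResult out;
    out.duration = t_c;
    out.transited = (state == 6);
    out.n_cycles = n_cycles;
    out.dislodged = dislodged;
    return out;
}

// [[Rcpp::export(name = ".simulate_transit_cpp")]]
List simulate_transit_cpp(int n, double k1, double k2, double k3, double p1,
                          double dt, double t_max, double seed,
                          double stream_offset = 0.0) {
    const double p_off = 1.0 - std::exp(-k3 * dt);
    const double p_bt  = 1.0 - std::exp(-k1 * dt);
    const double p_rec = 1.0 - std::exp(-k2 * dt);
    const uint64_t useed = (uint64_t)((int64_t)seed);
    const uint64_t off = (uint64_t)((int64_t)stream_offset);

    NumericVector duration(n);
    LogicalVector transited(n);
    IntegerVector n_cycles(n);
    LogicalVector dislodged(n);

    for (int i = 0; i < n; ++i) {
        TransitResult r = transit_one(p_off, p_bt, p_rec, p1, dt, t_max,
                                      stream_key(useed, off + (uint64_t)i));
        duration[i] = r.duration;
        transited[i] = r.transited;
        n_cycles[i] = r.n_cycles;
        dislodged[i] = r.dislodged;
    }

    return List::create(_["duration"] = duration,
                        _["transited"] = transited,
                        _["n_cycles"] = n_cycles,
                        _["dislodged"] = dislodged);
}
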