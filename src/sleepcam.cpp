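// Pixel-level core: sample-based background subtraction (ViBe-style) and the
// synthetic frame renderer. Both use an explicit xorshift64* PRNG whose state
// lives in the model object / per-frame seeds, so results are bit-reproducible
// and independent of R's RNG and of chunking.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct XS {
  uint64_t s;
  explicit XS(uint64_t seed) {
    s = splitmix64(seed);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  inline uint64_t nxt() {
    uint64_t x = s;
    x ^= x >> 12; x ^= x << 25; x ^= x >> 27;
    s = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  inline double unif() { return (nxt() >> 11) * (1.0 / 9007199254740992.0); }
  inline int below(int n) { return (int)(unif() * n); }
};

static inline uint64_t unpack_state(const IntegerVector& v) {
  uint64_t lo = (uint32_t)v[0], hi = (uint32_t)v[1];
  return (hi << 32) | lo;
}
static inline IntegerVector pack_state(uint64_t s) {
  IntegerVector v(2);
  v[0] = (int32_t)(uint32_t)(s & 0xFFFFFFFFULL);
  v[1] = (int32_t)(uint32_t)(s >> 32);
  return v;
}

static const int NB_DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int NB_DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Initialise the per-pixel sample buffer from the 8-neighbourhood of the first
// frame (clamped at borders), sampling with replacement.
// [[Rcpp::export]]
List vibe_init_cpp(IntegerMatrix frame, int n_samples, double seed) {
  const int h = frame.nrow(), w = frame.ncol();
  const int plane = h * w;
  IntegerVector samples(plane * n_samples);
  XS rng((uint64_t)::llround(seed));
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const int idx = c * h + r;
      for (int k = 0; k < n_samples; ++k) {
        const int o = rng.below(8);
        int nr = r + NB_DR[o], nc = c + NB_DC[o];
        if (nr < 0) nr = 0; else if (nr >= h) nr = h - 1;
        if (nc < 0) nc = 0; else if (nc >= w) nc = w - 1;
        samples[idx + plane * k] = frame(nr, nc);
      }
    }
  }
  samples.attr("dim") = IntegerVector::create(h, w, n_samples);
  return List::create(_["samples"] = samples, _["rng_state"] = pack_state(rng.s));
}

// Classify and update a block of frames. `frames` is h*w*nf column-major.
// A pixel is background iff >= min_matches samples lie within match_radius
// (inclusive) of its value. Background pixels self-update and spatially update
// one random 8-neighbour, each with probability 1/subsample_factor. A pixel
// foreground for `absorb_after` consecutive frames has min_matches random model
// slots seeded with its current value (static-foreground absorption);
// absorb_after = 0 disables absorption (pure conservative update).
// [[Rcpp::export]]
List vibe_run_cpp(IntegerVector samples, IntegerVector counter,
                  IntegerVector rng_state, IntegerVector frames,
                  int h, int w, int nf,
                  int n_samples, int match_radius, int min_matches,
                  int subsample_factor, int absorb_after, bool return_masks) {
  const int plane = h * w;
  IntegerVector S = clone(samples);
  IntegerVector C = clone(counter);
  IntegerVector counts(nf);
  IntegerVector masks = return_masks ? IntegerVector(plane * nf) : IntegerVector(0);
  XS rng(1);
  rng.s = unpack_state(rng_state);
  const double inv_phi = 1.0 / subsample_factor;

  for (int f = 0; f < nf; ++f) {
    const int* fr = INTEGER(frames) + (R_xlen_t)f * plane;
    int cnt = 0;
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        const int idx = c * h + r;
        const int v = fr[idx];
        int matches = 0;
        for (int k = 0; k < n_samples; ++k) {
          const int d = S[idx + plane * k] - v;
          if (d <= match_radius && d >= -match_radius) {
            if (++matches >= min_matches) break;
          }
        }
        if (matches >= min_matches) {           // background
          C[idx] = 0;
          if (rng.unif() < inv_phi)
            S[idx + plane * rng.below(n_samples)] = v;
          if (rng.unif() < inv_phi) {
            const int o = rng.below(8);
            int nr = r + NB_DR[o], nc = c + NB_DC[o];
            if (nr < 0) nr = 0; else if (nr >= h) nr = h - 1;
            if (nc < 0) nc = 0; else if (nc >= w) nc = w - 1;
            S[(nc * h + nr) + plane * rng.below(n_samples)] = v;
          }
        } else {                                 // foreground
          ++cnt;
          if (return_masks) masks[(R_xlen_t)f * plane + idx] = 1;
          if (absorb_after > 0 && ++C[idx] >= absorb_after) {
            // seed min_matches *distinct* slots so absorption completes now
            int slot = rng.below(n_samples);
            for (int m = 0; m < min_matches; ++m) {
              S[idx + plane * slot] = v;
              slot = (slot + 1 + rng.below(n_samples - 1)) % n_samples;
            }
            C[idx] = 0;
          }
        }
      }
    }
    counts[f] = cnt;
  }
  S.attr("dim") = IntegerVector::create(h, w, n_samples);
  List out = List::create(_["counts"] = counts, _["samples"] = S,
                          _["counter"] = C, _["rng_state"] = pack_state(rng.s));
  if (return_masks) {
    masks.attr("dim") = IntegerVector::create(h, w, nf);
    out["masks"] = masks;
  }
  return out;
}

// Render a block of synthetic cage frames: flat background plus an elliptical
// target, independent Gaussian pixel noise, optional small "ear flicker" patch.
// Noise is seeded per absolute frame index so output is chunk-invariant.
// [[Rcpp::export]]
IntegerVector render_frames_cpp(int h, int w, IntegerVector frame_idx,
                                NumericVector cx, NumericVector cy,
                                NumericVector ax, NumericVector ay,
                                double bg_level, double blob_level,
                                double noise_sd, double seed,
                                IntegerVector fx, IntegerVector fy,
                                IntegerVector fsize) {
  const int nf = frame_idx.size();
  const int plane = h * w;
  IntegerVector out((R_xlen_t)plane * nf);
  const uint64_t base = (uint64_t)::llround(seed);

  for (int f = 0; f < nf; ++f) {
    XS rng(splitmix64(base ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(frame_idx[f] + 1))));
    int* fr = INTEGER(out) + (R_xlen_t)f * plane;
    const double fcx = cx[f], fcy = cy[f], fax = ax[f], fay = ay[f];
    bool have_spare = false;
    double spare = 0.0;
    for (int c = 0; c < w; ++c) {
      const double dx = (c - fcx) / fax;
      const double dx2 = dx * dx;
      for (int r = 0; r < h; ++r) {
        const double dy = (r - fcy) / fay;
        double level = (dx2 + dy * dy <= 1.0) ? blob_level : bg_level;
        if (noise_sd > 0) {
          double z;
          if (have_spare) { z = spare; have_spare = false; }
          else {
            double u1 = rng.unif(), u2 = rng.unif();
            if (u1 < 1e-300) u1 = 1e-300;
            const double m = std::sqrt(-2.0 * std::log(u1));
            z = m * std::cos(2.0 * M_PI * u2);
            spare = m * std::sin(2.0 * M_PI * u2);
            have_spare = true;
          }
          level += noise_sd * z;
        }
        int vi = (int)::lround(level);
        if (vi < 0) vi = 0; else if (vi > 255) vi = 255;
        fr[c * h + r] = vi;
      }
    }
    if (fsize[f] > 0) {                          // ear-flicker patch
      for (int dc = 0; dc < fsize[f]; ++dc) {
        for (int dr = 0; dr < fsize[f]; ++dr) {
          const int pr = fy[f] + dr, pc = fx[f] + dc;
          if (pr >= 0 && pr < h && pc >= 0 && pc < w)
            fr[pc * h + pr] = (int)blob_level;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, nf);
  return out;
}
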