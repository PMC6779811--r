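# the Euler-Maruyama loop is the package's hot path; see theta_sim.cpp
PKG_CXXFLAGS = -O3 -funroll-loops
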