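{"n_photons":1000000,"seed":777,"tissue":{"mua":0.01,"mus":10,"g":0.9},"bone":{"mua":0.01,"mus":25,"g":0.9},"note":"high-N reference reflectances for the two-layer model (synthetic reference run)","reflectance":{"d2":0.794087931162785,"d10":0.749868507044004}}
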