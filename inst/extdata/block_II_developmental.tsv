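gene
Cdx
Cux1
Gdf1
Gdf3
Gdf5
Gdf10
Gdf15
Gsx
Pax3
Pax6
Srgap2
Gdf11
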