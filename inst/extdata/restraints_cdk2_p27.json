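[{"name":"p0_atp","group_a":{"chain":"P","resno":187},"group_b":{"chain":"X","resname":"ATP"},"max_distance":3.5},{"name":"p3_pt160","group_a":{"chain":"P","resno":190},"group_b":{"chain":"A","resno":160},"max_distance":3.5},{"name":"p3_i270","group_a":{"chain":"P","resno":190},"group_b":{"chain":"B","resno":270},"max_distance":3.5},{"name":"mg_coordination","group_a":{"chain":"X","resname":"MG"},"group_b":{"chain":"X","resname":["ATP","HOH"]},"max_distance":3}]
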