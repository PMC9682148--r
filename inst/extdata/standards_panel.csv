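"name","species","channel","q1_printed","q3_printed","dp","ep","ce","cxp","rt_min"
"MG-17:0","MG 17:0 (17:0)","acylium",362.3,253.3,60,10,21,14,2.3
"MG-17:1","MG 17:1 (17:1)","acylium",360.2,251.2,60,10,15,14,1.8
"MG-19:0","MG 19:0 (19:0)","dehydration",390.3,355.3,60,10,19,18,2.9
"MG-19:1","MG 19:1 (19:1)","acylium",388.3,279.1,60,10,15,14,2.3
"MG-19:2","MG 19:2 (19:2)","acylium",386.3,277.1,60,10,15,14,1.9
"MG-21:0","MG 21:0 (21:0)","dehydration",418.3,383.3,60,10,19,20,3.9
"MG-22:1","MG 22:1 (22:1)","acylium",430.3,321.3,60,10,21,18,3.2
"MG-24:1","MG 24:1 (24:1)","acylium",458.3,349.3,60,10,21,18,3.9
"DG-31:1[D5]","DG 31:1 (17:0_14:1)[D5]","loss:14:1",575.5,332.2,50,10,21,18,5.2
"DG-33:1[D5]","DG 33:1 (17:0_16:1)[D5]","loss:17:0",603.4,316.4,50,10,21,18,6
"DG-35:1[D5]","DG 35:1 (17:0_18:1)[D5]","loss:17:0",631.6,344.2,50,10,27,18,7.1
"DG-37:3[D5]","DG 37:3 (17:0_20:3)[D5]","loss:17:0",655.4,368.4,50,10,27,18,6.4
"DG-39:4[D5]","DG 39:4 (17:0_22:4)[D5]","loss:22:4",681.6,332.2,50,10,27,18,6.7
"DG-44:2","DG 44:2 (22:1_22:1)","loss:22:1",750.7,395.4,50,10,26,15,12.3
"DG-48:2","DG 48:2 (24:1_24:1)","loss:24:1",806.7,423.4,50,10,31,24,15.9
"TG-41:0[D5]","TG 41:0 (14:0_13:0_14:0)[D5]","loss:14:0",731.4,486.4,80,10,33,24,11.4
"TG-43:1[D5]","TG 43:1 (14:0_15:1_14:0)[D5]","loss:14:0",757.4,512.4,80,10,33,24,11.5
"TG-45:1[D5]","TG 45:1 (14:0_17:1_14:0)[D5]","loss:14:0",785.5,540.6,80,10,33,24,13.2
"TG-47:1[D5]","TG 47:1 (16:0_15:1_16:0)[D5]","loss:16:0",813.4,540.4,80,10,39,18,15.3
"TG-49:1[D5]","TG 49:1 (16:0_17:1_16:0)[D5]","loss:16:0",841.4,568.4,80,10,33,24,16.9
"TG-51:2[D5]","TG 51:2 (16:0_19:2_16:0)[D5]","loss:16:0",867.4,594.4,80,10,37,16,17.2
"TG-53:3[D5]","TG 53:3 (18:1_17:1_18:1)[D5]","loss:18:1",893.8,594.6,80,10,37,16,16.7
"TG-54:9","TG 54:9 (18:3_18:3_18:3)","loss:18:3",890.8,595.6,80,10,37,28,9.7
"TG-55:4[D5]","TG 55:4 (18:1_19:2_18:1)[D5]","loss:18:1",919.6,620.6,80,10,39,18,17
"TG-57:4[D5]","TG 57:4 (18:1_21:2_18:1)[D5]","loss:18:1",947.8,648.6,80,10,39,18,18.7
"TG-66:3","TG 66:3 (22:1_22:1_22:1)","loss:22:1",1071.1,715.8,80,10,43,32,25
"TG-72:3","TG 72:3 (24:1_24:1_24:1)","loss:24:1",1155.4,771.8,80,10,43,32,26.7
"MGDG-34:0","MGDG 34:0 (16:0_18:0)","carboxylate:18:0",757.6,283.2,-80,-10,-30,-15,2.8
"DGDG-36:0","DGDG 36:0 (18:0_18:0)","carboxylate:18:0",947.7,283.2,-180,-10,-40,-15,4.5
"LPC-15:0[D5]","LPC 15:0 (15:0)[D5]","carboxylate:15:0",545.4,241.2,-40,-10,-40,-13,5.3
"LPC-17:0[D5]","LPC 17:0 (17:0)[D5]","carboxylate:17:0",573.4,269.2,-40,-10,-40,-13,5.2
"LPC-19:0[D5]","LPC 19:0 (19:0)[D5]","carboxylate:19:0",601.4,297.3,-40,-10,-40,-13,5.1
"LPC-17:1","LPC 17:1 (17:1)","carboxylate:17:1",566.4,267.2,-40,-10,-40,-13,5.2
"LPE-15:0[D5]","LPE 15:0 (15:0)[D5]","carboxylate:15:0",443.4,241.2,-110,-10,-30,-13,7.7
"LPE-17:0[D5]","LPE 17:0 (17:0)[D5]","carboxylate:17:0",471.4,269.1,-110,-10,-30,-13,7.5
"LPE-19:0[D5]","LPE 19:0 (19:0)[D5]","carboxylate:19:0",499.4,297.3,-110,-10,-30,-13,7.3
"LPE-18:1","LPE 18:1 (18:1)","carboxylate:18:1",478.3,281.3,-110,-10,-30,-13,7.5
"LPG-15:0[D5]","LPG 15:0 (15:0)[D5]","carboxylate:15:0",474.3,241.1,-100,-10,-34,-17,9
"LPG-17:0[D5]","LPG 17:0 (17:0)[D5]","carboxylate:17:0",502.3,269.2,-100,-10,-34,-17,8.8
"LPG-19:0[D5]","LPG 19:0 (19:0)[D5]","carboxylate:19:0",530.4,297.2,-100,-10,-34,-17,8.7
"LPG-17:1","LPG 17:1 (17:1)","carboxylate:17:1",495.2,267.2,-100,-10,-34,-17,8.9
"LPI-15:0[D5]","LPI 15:0 (15:0)[D5]","carboxylate:15:0",562.4,241.2,-110,-10,-44,-13,10.1
"LPI-17:0[D5]","LPI 17:0 (17:0)[D5]","carboxylate:17:0",590.2,269.3,-110,-10,-44,-13,9.7
"LPI-19:0[D5]","LPI 19:0 (19:0)[D5]","carboxylate:19:0",618.4,297.2,-110,-10,-44,-13,9.5
"LPI-18:1","LPI 18:1 (18:1)","carboxylate:18:1",597.3,281.3,-110,-10,-44,-13,9.8
"LPS-15:0[D5]","LPS 15:0 (15:0)[D5]","headgroup_d5",487.4,158,-40,-10,-34,-9,12.4
"LPS-17:0[D5]","LPS 17:0 (17:0)[D5]","headgroup_d5",515.4,158,-40,-10,-34,-9,12
"LPS-19:0[D5]","LPS 19:0 (19:0)[D5]","headgroup_d5",543.3,158,-40,-10,-34,-9,11.7
"LPS-17:1","LPS 17:1 (17:1)","carboxylate:17:1",508.4,267.2,-40,-10,-34,-9,12.3
"PC-31:1[D5]","PC 31:1 (14:1_17:0)[D5]","carboxylate:14:1",781.6,225.2,-65,-10,-52,-15,3.9
"PC-33:1[D5]","PC 33:1 (16:1_17:0)[D5]","carboxylate:16:1",809.6,253.2,-65,-10,-52,-15,3.9
"PC-35:1[D5]","PC 35:1 (18:1_17:0)[D5]","carboxylate:18:1",837.6,281.2,-65,-10,-52,-15,3.9
"PC-37:3[D5]","PC 37:3 (20:3_17:0)[D5]","carboxylate:20:3",861.6,305.2,-65,-10,-52,-15,3.9
"PC-39:4[D5]","PC 39:4 (22:4_17:0)[D5]","carboxylate:22:4",887.6,331.2,-65,-10,-52,-15,3.8
"PE-31:1[D5]","PE 31:1 (14:1_17:0)[D5]","carboxylate:14:1",679.4,225.2,-120,-10,-38,-13,6.3
"PE-33:1[D5]","PE 33:1 (16:1_17:0)[D5]","carboxylate:16:1",707.6,253.2,-120,-10,-38,-13,6.2
"PE-35:1[D5]","PE 35:1 (18:1_17:0)[D5]","carboxylate:18:1",735.6,281.4,-120,-10,-38,-13,6.2
"PE-37:3[D5]","PE 37:3 (20:3_17:0)[D5]","carboxylate:20:3",759.6,305.2,-120,-10,-38,-13,6.1
"PE-39:4[D5]","PE 39:4 (22:4_17:0)[D5]","carboxylate:22:4",785.6,331.2,-120,-10,-38,-13,6.1
"PG-31:1[D5]","PG 31:1 (14:1_17:0)[D5]","carboxylate:14:1",710.6,225.2,-120,-10,-44,-13,7.6
"PG-33:1[D5]","PG 33:1 (16:1_17:0)[D5]","carboxylate:16:1",738.4,253.2,-120,-10,-44,-13,7.5
"PG-35:1[D5]","PG 35:1 (18:1_17:0)[D5]","carboxylate:18:1",766.5,281.3,-120,-10,-44,-13,7.5
"PG-37:3[D5]","PG 37:3 (20:3_17:0)[D5]","carboxylate:20:3",790.4,305.2,-120,-10,-44,-13,7.4
"PG-39:4[D5]","PG 39:4 (22:4_17:0)[D5]","carboxylate:22:4",816.4,331.2,-120,-10,-44,-13,7.4
"PI-31:1[D5]","PI 31:1 (14:1_17:0)[D5]","carboxylate:17:0",798.6,269.2,-55,-10,-60,-15,8.7
"PI-33:1[D5]","PI 33:1 (16:1_17:0)[D5]","carboxylate:16:1",826.6,253.2,-55,-10,-60,-15,8.6
"PI-35:1[D5]","PI 35:1 (18:1_17:0)[D5]","carboxylate:18:1",854.6,281.2,-55,-10,-60,-15,8.5
"PI-37:3[D5]","PI 37:3 (20:3_17:0)[D5]","carboxylate:20:3",878.6,305.2,-55,-10,-60,-15,8.5
"PI-39:4[D5]","PI 39:4 (22:4_17:0)[D5]","carboxylate:22:4",904.6,331.2,-55,-10,-60,-15,8.4
"PS-31:1[D5]","PS 31:1 (14:1_17:0)[D5]","carboxylate:17:0",723.6,269.3,-60,-10,-50,-13,10.1
"PS-33:1[D5]","PS 33:1 (16:1_17:0)[D5]","carboxylate:16:1",751.6,253.2,-60,-10,-50,-13,10
"PS-35:1[D5]","PS 35:1 (18:1_17:0)[D5]","carboxylate:17:0",779.6,269.3,-60,-10,-50,-13,9.8
"PS-37:3[D5]","PS 37:3 (20:3_17:0)[D5]","carboxylate:20:3",803.6,305.2,-60,-10,-50,-13,9.7
"PS-39:4[D5]","PS 39:4 (22:4_17:0)[D5]","carboxylate:22:4",829.6,331.2,-60,-10,-50,-13,9.6
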