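sample_id,tree_id,location,cohort,putative_cultivar,pomological_cultivar,trueness,ploidy,CH01h01,CH01f07a,CH03d07,CH04c07,CH05f06,CH01f03b,GD12,CH02d08,CH05e03,CH02c09,CH02g09,CH01f02,CH04f10,COL,Hi02c07,CH04e05,GD147
S00001,T00001,L6,P2009_2014,CV_001,CV_001,5,2,118:198,117:231,138:213,105:260,244:256,145:208,154:226,114:243,183:248,148:165,119:125,140:229,143:232,134:173,162:169:217,119:238:250,181:202
S00002,T00002,L2,P2009_2014,CV_001,CV_001,1,2,118:198,117:231,138:213,105:260,244:256,145:208,154:226,114:243,183:248,148:165,119:125,140:229,143:232,134:173,162:169:217,119:238:250,181:202
S00003,T00003,L3,P2009_2014,CV_001,CV_001,1,2,118:198,117:231,138:213,105:260,244:256,145:208,154:226,114:243,184:248,148:165,119:125,140:229,0,134:173,162:169:217,0,181:202
S00004,T00004,L8,P2009_2014,CV_001,CV_001,1,2,118:198,117:231,138:213,105:260,244:256,145:208,154:226,114:243,183:248,148:165,119:125,140:229,144:232,134:173,162:169:217,119:238:250,181:202
S00005,T00005,L5,P2009_2014,CV_001,CV_001,3,2,118:198,117:231,138:213,105:260,244:256,145:208,154:226,114:243,183:248,148:165,119:125,140:229,143:232,134:173,162:169:217,119:238:250,181:202
S00006,T00006,L3,P2017_2021,CV_002,CV_002,1,3,100:126,109:121:231,95:156:253,157:212:235,147:238:239,110:120:153,102:113:140,97:159:166,99:242:250,114:138:148,121:142:146,124:139:173,155:168:239,110:135:137,169:183:208,156:199:250,160:224:228
S00007,T00007,L4,P2017_2021,CV_002,CV_002,4,3,100:126,109:121:231,95:156:252,157:212:235,147:238:239,0,102:113:140,97:159:166,99:242:250,114:138:148,121:142:146,124:139:173,155:168:239,110:135:137,169:183:208,156:199:250,161:224:228
S00008,T00008,L7,P2009_2014,CV_002,CV_002,1,3,100:126,109:121:231,95:156:253,157:212:235,147:238:239,110:120:153,102:112:140,97:159:166,99:242:250,114:138:148,121:140:146,124:139:173,0,110:135:137,168:183:208,156:199:250,160:224:228
S00009,T00009,L4,P2017_2021,CV_003,CV_003,5,2,100:118,170:251,143:204,196:235,91:103,202:253,149:154,97:243,130:183,138:215,129:137,101:188,248:254,120:137,0,138:238,236
S00010,T00010,L7,P2009_2014,CV_003,CV_003,R,2,100:118,170:251,143:204,196:235,91:103,202:253,149:154,0,130:183,138:215,127:135,101:188,248:254,120:137,120:169,138:238,236
S00011,T00011,L3,P2017_2021,CV_003,CV_003,4,2,100:118,170:251,143:204,196:235,91:103,202:253,149:154,97:243,130:183,138:215,0,101:188,248:254,120:137,120:169,138:238,236
S00012,T00012,L8,P2017_2021,CV_003,CV_003,1,2,100:118,170:251,143:204,196:235,91:103,202:253,149:154,97:243,0,138:214,129:137,101:188,248:254,120:137,120:169,138:238,236
S00013,T00013,L8,P2009_2014,CV_003,CV_003,4,2,100:118,0,143:204,196:235,91:103,202:253,0,97:243,130:183,138:215,127:135,101:188,248:254,120:137,120:169,138:238,236
S00014,T00014,L1,P2017_2021,CV_003,CV_003,5,2,100:118,170:251,143:204,196:235,91:103,202:253,149:154,0,130:183,138:215,129:137,101:188,248:254,120:137,120:169,138:238,236
S00015,T00015,L2,P2009_2014,CV_004,CV_004,1,2,134,251:260,162:220,235:260,91:244,120:253,97:140,114:126,183:248,138:140,0,135:187,122:232,134:185,184:217,125:260,133:236
S00016,T00016,L4,P2009_2014,CV_004,CV_004,2,2,134,251:260,162:220,235:260,91:244,120:253,97:140,114:126,183:248,138:140,122:131,135:187,122:232,134:185,184:217,125:260,132:236
S00017,T00017,L5,P2009_2014,CV_005,CV_005,2,2,118:126,173:218,179,116:235,147:212,110:169,222:228,114:126,183:248,148:184,125:136,104:188,108:248,146:238,162:183,139:186,160:204
S00018,T00018,L8,P2017_2021,CV_005,CV_005,3,2,118:126,173:218,180,116:235,146:212,110:169,222:228,114:126,183:248,148:184,127:138,104:188,108:248,0,162:183,139:186,160:204
S00019,T00019,L6,P2017_2021,CV_005,CV_005,2,2,118:126,173:218,179,116:235,147:212,110:169,222:228,114:126,183:248,148:184,127:138,104:188,108:248,146:238,162:183,139:186,160:204
S00020,T00020,L5,P2009_2014,CV_005,CV_005,1,2,118:126,173:218,179,116:235,147:212,110:169,0,115:126,183:248,148:184,125:136,104:188,108:248,146:238,162:183,139:186,160:204
S00021,T00021,L6,P2009_2014,CV_006,CV_006,5,2,118:194,139:251,143:226,157:260,91:148,111:120,129:139,103:159,183:250,224:246,118:131,135:160,143:155,137:147,143:192,0,103:228
S00022,T00022,L1,P2009_2014,CV_006,CV_006,1,2,118:194,139:251,143:226,157:260,91:148,111:120,129:139,103:159,183:250,224:246,118:131,0,143:155,137:147,143:192,0,103:228
S00023,T00023,L2,P2017_2021,CV_007,CV_007,1,2,100:134,137:139,143:253,196:229,238:239,145:253,220:222,103:149,192:242,115:242,124:135,139:140,130:254,134:174,103:120,221:260,223:228
S00024,T00024,L2,P2009_2014,CV_007,CV_007,1,2,100:134,137:139,143:253,196:229,238:239,145:253,220:222,103:149,192:242,116:242,122:133,139:140,130:254,134:174,103:120,221:260,223:228
S00025,T00025,L6,P2009_2014,CV_007,CV_007,5,2,100:134,137:139,143:252,196:229,238:239,145:253,220:222,103:149,192:243,115:242,122:133,139:140,130:254,134:174,103:120,221:260,223:228
S00026,T00026,L3,P2009_2014,CV_007,CV_007,2,2,100:134,137:139,143:253,196:229,238:239,145:253,220:222,103:148,192:242,115:242,122:133,139:140,0,134:174,103:120,221:260,223:228
S00027,T00027,L6,P2017_2021,CV_007,CV_007,1,2,100:134,0,143:253,196:229,238:239,145:253,220:222,104:149,192:241,115:242,124:135,139:140,130:254,134:174,103:120,221:260,223:228
S00028,T00028,L2,P2009_2014,CV_008,CV_008,3,2,211:234,115:194,162:223,229:235,198:236,202:253,105:149,243,183,99:114,118:131,166:229,130:182,120:235,169:192,0,223:224
S00029,T00029,L7,P2009_2014,CV_008,CV_008,R,2,211:234,115:194,162:223,229:235,198:236,202:252,105:149,243,183,99:114,118:131,166:229,0,120:235,169:192,119:199,223:224
S00030,T00030,L7,P2009_2014,CV_008,CV_008,R,2,211:234,115:194,162:224,0,198:236,202:253,105:149,243,183,99:114,118:131,166:229,130:182,120:235,169:192,119:199,223:224
S00031,T00031,L1,P2009_2014,CV_008,CV_008,4,2,211:234,115:194,162:223,229:235,198:236,202:253,105:149,243,183,99:114,118:131,166:229,130:182,120:235,169:192,119:199,223:224
S00032,T00032,L4,P2009_2014,CV_008,CV_008,1,2,211:234,115:194,162:223,229:235,198:236,202:253,105:149,243,184,99:114,118:131,166:229,130:182,120:235,169:192,119:199,223:224
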