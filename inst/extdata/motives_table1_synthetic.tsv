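motive	category	seeds
Regeneration	regenerative	SYN0001;SYN0002;SYN0003;SYN0004;SYN0005;SYN0006;SYN0007;SYN0008;SYN0009;SYN0010;SYN0011;SYN0012;SYN0013;SYN0014;SYN0015;SYN0016;SYN0017;SYN0018;SYN0019;SYN0020;SYN0021;SYN0022;SYN0023;SYN0024;SYN0025;SYN0026;SYN0027;SYN0028
Apoptosis axotomy	regenerative	SYN0029;SYN0030;SYN0031;SYN0032;SYN0033;SYN0034;SYN0035;SYN0036;SYN0037;SYN0038;SYN0039;SYN0040;SYN0041;SYN0042;SYN0043;SYN0044;SYN0045;SYN0046;SYN0047;SYN0048;SYN0049;SYN0050;SYN0051;SYN0052;SYN0053;SYN0054;SYN0055;SYN0056;SYN0057;SYN0058;SYN0059;SYN0060;SYN0061;SYN0062
Anti apoptosis	regenerative	SYN0063;SYN0064;SYN0065;SYN0066;SYN0067;SYN0068;SYN0069;SYN0070;SYN0071;SYN0072;SYN0073;SYN0074;SYN0075;SYN0076;SYN0077;SYN0078;SYN0079;SYN0080;SYN0081;SYN0082;SYN0083;SYN0084;SYN0085;SYN0086;SYN0087;SYN0088;SYN0089;SYN0090;SYN0091;SYN0092
Pro-oxidants	regenerative	SYN0093;SYN0094;SYN0095;SYN0096;SYN0097;SYN0098;SYN0099
Anti-oxidants	regenerative	SYN0100;SYN0101;SYN0102;SYN0103;SYN0104;SYN0105;SYN0106;SYN0107;SYN0108;SYN0109;SYN0110;SYN0111;SYN0112;SYN0113;SYN0114;SYN0115;SYN0116;SYN0117;SYN0118;SYN0119;SYN0120
Inhibitor of necrosis	regenerative	SYN0121;SYN0122;SYN0123
Anti-anoikis	regenerative	SYN0124;SYN0125;SYN0126;SYN0127;SYN0128;SYN0129;SYN0130;SYN0131;SYN0132;SYN0133;SYN0134;SYN0135;SYN0136;SYN0137;SYN0138;SYN0139;SYN0140;SYN0141;SYN0142;SYN0143;SYN0144;SYN0145;SYN0146;SYN0147;SYN0148;SYN0149
Anti-aging	regenerative	SYN0150;SYN0151;SYN0152;SYN0153;SYN0154;SYN0155
ROS hormesis	regenerative	SYN0156;SYN0157;SYN0158;SYN0159;SYN0160;SYN0161;SYN0162;SYN0163;SYN0164;SYN0165;SYN0166;SYN0167;SYN0168;SYN0169;SYN0170;SYN0171;SYN0172;SYN0173;SYN0174;SYN0175;SYN0176
Mitochondria well function	regenerative	SYN0177;SYN0178;SYN0179;SYN0180;SYN0181;SYN0182;SYN0183;SYN0184;SYN0185;SYN0186;SYN0187;SYN0188
Autophagosome fusion events	degenerative	SYN0189;SYN0190;SYN0191;SYN0192;SYN0193;SYN0194;SYN0195;SYN0196;SYN0197;SYN0198;SYN0199;SYN0200;SYN0201;SYN0202;SYN0203;SYN0204;SYN0205;SYN0206;SYN0207;SYN0208;SYN0209;SYN0210;SYN0211;SYN0212;SYN0213;SYN0214;SYN0215;SYN0216;SYN0217;SYN0218;SYN0219;SYN0220;SYN0221;SYN0222;SYN0223;SYN0224;SYN0225;SYN0226;SYN0227;SYN0228;SYN0229;SYN0230;SYN0231;SYN0232;SYN0233;SYN0234;SYN0235;SYN0236;SYN0237;SYN0238;SYN0239;SYN0240;SYN0241;SYN0242;SYN0243;SYN0244
Selective autophagy	degenerative	SYN0245;SYN0246;SYN0247;SYN0248;SYN0249;SYN0250;SYN0251;SYN0252;SYN0253;SYN0254;SYN0255;SYN0256;SYN0257;SYN0258;SYN0259;SYN0260;SYN0261;SYN0262
Necrosis	degenerative	SYN0263;SYN0264;SYN0265;SYN0266;SYN0267;SYN0268;SYN0269;SYN0270;SYN0271;SYN0272;SYN0273;SYN0274;SYN0275;SYN0276;SYN0277;SYN0278;SYN0279;SYN0280;SYN0281;SYN0282;SYN0283;SYN0284;SYN0285;SYN0286;SYN0287;SYN0288;SYN0289;SYN0290;SYN0291
Anoikis	degenerative	SYN0292;SYN0293;SYN0294;SYN0295;SYN0296;SYN0297;SYN0298;SYN0299;SYN0300
Rearrangements of cytoskeleton & organelles	degenerative	SYN0301;SYN0302;SYN0303;SYN0304;SYN0305;SYN0306;SYN0307
Mitochondria related-events	degenerative	SYN0308;SYN0309;SYN0310;SYN0311;SYN0312;SYN0313;SYN0314;SYN0315;SYN0316;SYN0317;SYN0318
Nucleolar stress	degenerative	SYN0319;SYN0320;SYN0321;SYN0322;SYN0323;SYN0324;SYN0325;SYN0326;SYN0327;SYN0328;SYN0329;SYN0330;SYN0331;SYN0332;SYN0333;SYN0334;SYN0335;SYN0336;SYN0337;SYN0338;SYN0339;SYN0340;SYN0341;SYN0342;SYN0343;SYN0344;SYN0345;SYN0346;SYN0347;SYN0348;SYN0349;SYN0350
ER stress	degenerative	SYN0351;SYN0352;SYN0353;SYN0354;SYN0355;SYN0356;SYN0357
Pain	degenerative	SYN0358;SYN0359;SYN0360;SYN0361;SYN0362;SYN0363;SYN0364;SYN0365;SYN0366;SYN0367;SYN0368;SYN0369;SYN0370;SYN0371;SYN0372;SYN0373;SYN0374;SYN0375;SYN0376;SYN0377;SYN0378;SYN0379;SYN0380;SYN0381;SYN0382;SYN0383
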