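(((((((((ASV_049:0.05989863823,ASV_016:0.05989863823):0.03404477422,(((ASV_052:0.01099656168,ASV_029:0.01099656168):0.009921243803,ASV_041:0.02091780549):0.01027249158,ASV_013:0.03119029707):0.06275311538):0.09421722579,((ASV_007:0.07198426772,((((ASV_035:0.02750475811,ASV_011:0.02750475811):0.001357805515,ASV_042:0.02886256362):0.02291280895,((ASV_045:0.0004506565528,ASV_055:0.0004506565528):0.02032566962,(ASV_030:0.02035073992,ASV_033:0.02035073992):0.0004255862485):0.0309990464):0.004140316464,(ASV_056:0.004527789172,ASV_040:0.004527789172):0.05138789987):0.01606857868):0.004059993873,((ASV_012:0.02217633376,(ASV_048:0.003201156647,(ASV_009:0.0001218699116,ASV_025:0.0001218699116):0.003079286735):0.01897517712):0.0299175755,ASV_051:0.05209390926):0.02395035233):0.1121163767):0.02148246281,((ASV_005:0.06127980116,((ASV_038:0.0103251721,ASV_047:0.0103251721):0.004392498484,ASV_017:0.01471767058):0.04656213058):0.0534875403,(((ASV_053:0.05744703297,ASV_034:0.05744703297):0.004670904074,ASV_018:0.06211793704):0.01034774655,(ASV_050:0.06567330349,ASV_043:0.06567330349):0.006792380098):0.04230165787):0.09487575959):0.009393257454,((((ASV_004:0.0113723892,ASV_027:0.0113723892):0.02285896548,ASV_060:0.03423135468):0.09274608697,(ASV_057:0.08233442997,ASV_019:0.08233442997):0.04464301169):0.03490475276,((ASV_014:0.02205464708,ASV_031:0.02205464708):0.0212257142,ASV_008:0.04328036128):0.1186018331):0.05715416409):0.3669776524,ASV_023:0.5860140109):0.106449316,((ASV_026:0.3627789403,((ASV_001:0.02153139015,ASV_058:0.02153139015):0.0216301997,ASV_054:0.04316158984):0.3196173504):0.02494965046,(ASV_032:0.00251874466,ASV_020:0.00251874466):0.3852098461):0.3047347362):0.7498492831,(((ASV_006:0.008439415859,(ASV_024:0.002691920514,ASV_022:0.002691920514):0.005747495344):0.01438422395,ASV_003:0.02282363981):0.1906103299,((ASV_044:0.04310788483,ASV_021:0.04310788483):0.1091409883,((ASV_002:0.009648672654,ASV_015:0.009648672654):0.01364661154,ASV_036:0.0232952842):0.1289535889):0.06118509657):1.22887864):1.84844503,(((ASV_039:0.007064460518,ASV_037:0.007064460518):0.03949144943,(ASV_010:0.04392187806,ASV_028:0.04392187806):0.002634031884):0.7406973103,(ASV_059:0.005990489599,ASV_046:0.005990489599):0.7812627307):2.50350442);
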