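(((((t18:7.93639530580421,(t19:4.64105401386116,(t97:1.08522255366792,t72:1.08522255366792):3.55583146019324):3.29534129194305):6.43793918515684,(t5:5.23949700487294,t75:5.23949700487294):9.13483748608811):0.32588722830648,((t4:11.7011216592637,(((t35:5.62991224963019,(t67:2.664598569188,(t74:0.0362077695154274,t121:0.0362077695154274):2.62839079967257):2.96531368044219):0.138023725101298,(t9:3.62739210002302,(t64:3.02878244858208,t69:3.02878244858208):0.598609651440934):2.14054387470847):1.34288398546021,(t39:5.15877062435461,(t24:2.36191363962593,(t77:2.24975862438263,t80:2.24975862438263):0.112155015243305):2.79685698472867):1.95204933583709):4.59030169907199):1.29591370624868,(((t13:7.5434038538129,t21:7.5434038538129):2.51466937424657,(((t41:4.90618929251138,(t61:3.73233168162548,(t6:2.85103800536235,t108:2.85103800536235):0.881293676263128):1.1738576108859):2.18138682092033,(t25:4.79148262621589,(t42:1.09103125973575,t96:1.09103125973575):3.70045136648014):2.29609348721582):0.369615861631155,(t22:4.67770222109104,t46:4.67770222109104):2.77948975397182):2.60088125299662):0.221487741803586,((t52:4.24108187552021,(t10:0.921488013900671,t100:0.921488013900671):3.31959386161954):1.73410690631506,(t98:0.939644883350979,(t30:0.0604518474658186,t119:0.0604518474658186):0.879193035885161):5.03554389848429):4.30437218802779):2.7174743956493):1.70318635375517):0.49673856735225,((((t8:8.20489389100432,((t17:6.62344796435272,((t28:3.82911850476234,(t55:2.27807044003572,(t78:0.213789719425595,t116:0.213789719425595):2.06428072061013):1.55104806472662):0.6456840619243,t93:4.47480256668664):2.14864539766608):0.968925321323546,((((t54:3.73585678323333,t60:3.73585678323333):0.250443807563477,(t68:3.13540565474845,(t20:1.2404128932496,(t88:0.855843097316297,t102:0.855843097316297):0.384569795933306):1.89499276149885):0.850894936048355):0.646703319351367,(t86:1.84621427077343,(t101:0.268632201210445,t114:0.268632201210445):1.57758206956298):2.78678963937474):1.21656926827514,(t57:3.7622455329077,t31:3.7622455329077):2.08732764551562):1.74280010725295):0.612520605328052):1.88531391298845,(t12:3.49449208238064,t66:3.49449208238064):6.59571572161213):0.0545138880359469,((t27:6.65606872926931,t89:6.65606872926931):1.82353772593496,((t16:3.99618478595248,(t53:2.79819208920108,t71:2.79819208920108):1.1979926967514):0.770676826880955,(t43:2.00469649497886,t83:2.00469649497886):2.76216511785457):3.71274484237083):1.66511523682445):1.5948848848331,(((((t92:0.720074758017669,t106:0.720074758017669):0.130899327957155,t103:0.850974085974824):4.89149295907878,(t26:0.59424703614591,t110:0.59424703614591):5.14822000890769):1.32593573229877,(t2:2.0525099130554,(t81:0.538893971860446,t111:0.538893971860446):1.51361594119496):5.01589286429697):0.116481891802444,((t23:5.2742321196799,((t90:4.72766498127918,(t45:0.936424801906534,t99:0.936424801906534):3.79124017937265):0.249443341095208,(t91:0.622285636586976,t109:0.622285636586976):4.35482268578741):0.297123797305512):0.932263344225428,(t59:3.74006640983631,(t29:3.67267869456956,t122:3.67267869456956):0.0673877152667538):2.46642905406902):0.978389205249487):4.554721907707):3.45735370975796):1.00303971338022,((((t118:4.57071738692711,(t50:0.743602907111808,t105:0.743602907111808):3.8271144798153):4.21627869311355,(t58:3.74674340975131,(t65:0.459901448635945,t112:0.459901448635945):3.28684196111537):5.04025267028935):0.225516271603702,t1:9.01251235164436):2.89355782889366,(t32:5.81535075917106,(t36:5.3646361205542,(t7:4.60062252890783,t49:4.60062252890783):0.764013591646377):0.450714638616852):6.09071942136697):4.29392981946197);
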