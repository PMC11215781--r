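wavenumber,vcd
1600,0.0932622
1601,0.00535431
1602,0.116158
1603,0.191178
1604,0.0557345
1605,-0.0244684
1606,0.0596607
1607,-0.0120194
1608,-0.0518298
1609,0.105489
1610,-0.0594529
1611,-0.263684
1612,-0.0632509
1613,0.114914
1614,0.160173
1615,-0.0291083
1616,-0.00783985
1617,0.0627534
1618,-0.197196
1619,0.365009
1620,-0.0365603
1621,0.110662
1622,0.429496
1623,0.102716
1624,-0.013808
1625,-0.18866
1626,-0.125221
1627,0.0303492
1628,-0.0174942
1629,0.175679
1630,-0.0435862
1631,0.450396
1632,0.0847062
1633,0.505753
1634,0.519232
1635,0.689966
1636,1.26863
1637,1.43834
1638,2.32558
1639,2.95077
1640,3.68739
1641,4.45816
1642,4.90596
1643,5.67758
1644,6.16382
1645,7.10678
1646,7.25328
1647,7.53148
1648,7.62902
1649,7.35453
1650,6.9262
1651,6.12027
1652,5.59754
1653,5.02989
1654,4.13515
1655,3.46282
1656,2.65077
1657,1.73171
1658,1.10083
1659,0.584986
1660,0.0893281
1661,-0.495697
1662,-1.13283
1663,-1.65036
1664,-2.72879
1665,-3.67068
1666,-4.21678
1667,-4.92613
1668,-5.36397
1669,-6.36647
1670,-6.88426
1671,-7.39074
1672,-7.62158
1673,-7.86011
1674,-7.39993
1675,-6.78667
1676,-6.47547
1677,-5.50494
1678,-5.10952
1679,-4.33874
1680,-3.66451
1681,-2.58395
1682,-2.15774
1683,-1.8204
1684,-1.22615
1685,-0.883815
1686,-0.418583
1687,-0.566338
1688,-0.433113
1689,-0.0254405
1690,-0.0164223
1691,-0.203052
1692,0.218205
1693,-0.00917346
1694,-0.0766082
1695,-0.165011
1696,-0.279609
1697,-0.226639
1698,-0.124395
1699,0.0321413
1700,0.103546
1701,-0.0383441
1702,0.15658
1703,0.0356061
1704,-0.199399
1705,-0.0114687
1706,-0.189514
1707,0.225468
1708,0.0505285
1709,0.183928
1710,-0.180004
1711,-0.0649907
1712,-0.0468894
1713,-0.286107
1714,-0.0209628
1715,0.174525
1716,-0.224704
1717,-0.0070139
1718,-0.0331195
1719,-0.0515804
1720,-0.0962522
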